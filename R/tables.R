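# Embedded reference tables used across the package. All are standard published
# sets; sources are given per table so users can swap in alternatives.

#' @keywords internal
AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

#' @keywords internal
AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' @keywords internal
AA3_TO_1 <- stats::setNames(names(AA3), AA3)

# Average residue masses in Da (monomer minus water), IUPAC/Expasy values.
# A free peptide adds one water (18.0153 Da).
#' @keywords internal
AA_RESIDUE_MASS <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

#' @keywords internal
WATER_MASS <- 18.0153

# Theoretical maximum accessible surface areas per residue type (A^2),
# Tien et al. 2013 (PLoS ONE 8:e80635), "theoretical" column. Used to
# normalise residue SASA into relative SASA.
#' @keywords internal
MAX_ASA <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223, G = 104,
  H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
  T = 172, W = 285, Y = 263, V = 174)

# Van der Waals radii (A), Bondi 1964 set for the elements that dominate
# protein structures. Unknown elements fall back to carbon (1.70 A).
#' @keywords internal
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
               SE = 1.90)

#' @keywords internal
VDW_FALLBACK <- 1.70

# Grantham (1974) amino-acid distance matrix (Science 185:862-864).
# Symmetric, zero diagonal; used by the documented surrogate ddG model.
#' @keywords internal
GRANTHAM <- local({
  ord <- c("S","R","L","P","T","A","V","G","I","F",
           "Y","C","H","Q","N","K","D","E","M","W")
  upper <- list(
    S = c(R=110,L=145,P= 74,T= 58,A= 99,V=124,G= 56,I=142,F=155,Y=144,
          C=112,H= 89,Q= 68,N= 46,K=121,D= 65,E= 80,M=135,W=177),
    R = c(L=102,P=103,T= 71,A=112,V= 96,G=125,I= 97,F= 97,Y= 77,C=180,
          H= 29,Q= 43,N= 86,K= 26,D= 96,E= 54,M= 91,W=101),
    L = c(P= 98,T= 92,A= 96,V= 32,G=138,I=  5,F= 22,Y= 36,C=198,H= 99,
          Q=113,N=153,K=107,D=172,E=138,M= 15,W= 61),
    P = c(T= 38,A= 27,V= 68,G= 42,I= 95,F=114,Y=110,C=169,H= 77,Q= 76,
          N= 91,K=103,D=108,E= 93,M= 87,W=147),
    T = c(A= 58,V= 69,G= 59,I= 89,F=103,Y= 92,C=149,H= 47,Q= 42,N= 65,
          K= 78,D= 85,E= 65,M= 81,W=128),
    A = c(V= 64,G= 60,I= 94,F=113,Y=112,C=195,H= 86,Q= 91,N=111,K=106,
          D=126,E=107,M= 84,W=148),
    V = c(G=109,I= 29,F= 50,Y= 55,C=192,H= 84,Q= 96,N=133,K= 97,D=152,
          E=121,M= 21,W= 88),
    G = c(I=135,F=153,Y=147,C=159,H= 98,Q= 87,N= 80,K=127,D= 94,E= 98,
          M=127,W=184),
    I = c(F= 21,Y= 33,C=198,H= 94,Q=109,N=149,K=102,D=168,E=134,M= 10,
          W= 61),
    F = c(Y= 22,C=205,H=100,Q=116,N=158,K=102,D=177,E=140,M= 28,W= 40),
    Y = c(C=194,H= 83,Q= 99,N=143,K= 85,D=160,E=122,M= 36,W= 37),
    C = c(H=174,Q=154,N=139,K=202,D=154,E=170,M=196,W=215),
    H = c(Q= 24,N= 68,K= 32,D= 81,E= 40,M= 87,W=115),
    Q = c(N= 46,K= 53,D= 61,E= 29,M=101,W=130),
    N = c(K= 94,D= 23,E= 42,M=142,W=174),
    K = c(D=101,E= 56,M= 95,W=110),
    D = c(E= 45,M=160,W=181),
    E = c(M=126,W=152),
    M = c(W= 67))
  m <- matrix(0, 20, 20, dimnames = list(ord, ord))
  for (a in names(upper)) for (b in names(upper[[a]])) {
    m[a, b] <- upper[[a]][[b]]
    m[b, a] <- upper[[a]][[b]]
  }
  m[AA1, AA1]
})

# Most-used codon per amino acid in highly expressed E. coli genes
# (Kazusa codon usage database, E. coli K-12). User-overridable in
# back_translate(); vendor-optimised constructs will differ.
#' @keywords internal
ECOLI_CODON <- c(
  A = "GCG", R = "CGT", N = "AAC", D = "GAT", C = "TGC", Q = "CAG",
  E = "GAA", G = "GGC", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCG", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAT", V = "GTG")

# IUPAC degenerate nucleotide alphabet.
#' @keywords internal
IUPAC_NT <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A","G"), Y = c("C","T"), S = c("C","G"), W = c("A","T"),
  K = c("G","T"), M = c("A","C"),
  B = c("C","G","T"), D = c("A","G","T"), H = c("A","C","T"),
  V = c("A","C","G"), N = c("A","C","G","T"))
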