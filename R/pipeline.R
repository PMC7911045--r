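# One-command orchestration of the scaffold-selection workflow:
# candidate filter -> solvent accessibility -> conservation -> mutability ->
# mutable-residue selection -> patch detection and completion -> library
# design. Per-stage tables are persisted so any stage can be re-run and
# audited; a structured log records counts at each stage (the selection
# funnel) and every effective parameter.

#' Build and validate a pipeline configuration
#'
#' Defaults follow the published workflow where it states a value
#' (conservation < 90\%, mutability > 50\%, ddG tolerance 0.5 kcal/mol,
#' patch window 10--12, NNK codon); the contact cutoff (8.0 A) and
#' relative-SASA surface threshold (0.25) are package defaults.
#'
#' @param structure Path to the structure file (required).
#' @param msa Path to the MSA (optional; without it conservation is skipped
#'   and the conservation gate is disabled).
#' @param ddg Path to a position-scan ddG TSV; if \code{NULL} the documented
#'   surrogate model is used (\code{use_surrogate} then reports TRUE).
#' @param ref_id Reference record id in the MSA.
#' @param chain Chain to analyse (default: first chain).
#' @param cons_max,mut_min,ddg_threshold,rsasa_threshold,contact_cutoff
#'   Selection thresholds; see module functions.
#' @param patch_min,patch_max Patch completion window.
#' @param codon Degenerate codon for the library (default \code{"NNK"}).
#' @param design_library Design a library over the top patch (default TRUE).
#' @param probe_radius,n_points SASA parameters.
#' @param out_dir Output directory (default: a fresh temporary directory).
#' @param seed Seed recorded in the run log and used by any stochastic step.
#' @return A validated \code{PipelineConfig} list.
#' @export
pipeline_config <- function(structure, msa = NULL, ddg = NULL, ref_id = NULL,
                            chain = NULL, cons_max = 90, mut_min = 50,
                            ddg_threshold = 0.5, rsasa_threshold = 0.25,
                            contact_cutoff = 8.0, patch_min = 10,
                            patch_max = 12, codon = "NNK",
                            design_library = TRUE, probe_radius = 1.4,
                            n_points = 960, out_dir = tempfile("scaffpatch_"),
                            seed = 1) {
  fail <- function(...) stop("config error: ", ..., call. = FALSE)
  if (missing(structure) || !file.exists(structure))
    fail("structure file not found: ",
         if (missing(structure)) "<missing>" else structure)
  if (!is.null(msa) && !file.exists(msa)) fail("msa file not found: ", msa)
  if (!is.null(ddg) && !file.exists(ddg)) fail("ddg file not found: ", ddg)
  if (cons_max < 0 || cons_max > 100) fail("cons_max must lie in [0, 100]")
  if (mut_min < 0 || mut_min > 100) fail("mut_min must lie in [0, 100]")
  if (rsasa_threshold < 0 || rsasa_threshold > 1)
    fail("rsasa_threshold must lie in [0, 1]")
  if (contact_cutoff <= 0) fail("contact_cutoff must be positive")
  if (patch_min < 1 || patch_max < patch_min)
    fail("patch window must satisfy 1 <= patch_min <= patch_max")
  if (n_points < 24) fail("n_points must be >= 24")
  structure(list(structure = structure, msa = msa, ddg = ddg,
                 ref_id = ref_id, chain = chain, cons_max = cons_max,
                 mut_min = mut_min, ddg_threshold = ddg_threshold,
                 rsasa_threshold = rsasa_threshold,
                 contact_cutoff = contact_cutoff, patch_min = patch_min,
                 patch_max = patch_max, codon = codon,
                 design_library = design_library,
                 probe_radius = probe_radius, n_points = n_points,
                 out_dir = out_dir, seed = seed,
                 use_surrogate = is.null(ddg)),
            class = "PipelineConfig")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path Config file; keys as in \code{\link{pipeline_config}}. Relative
#'   input paths are resolved against the config file's directory.
#' @return A validated \code{PipelineConfig}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  base_dir <- dirname(normalizePath(path))
  for (k in c("structure", "msa", "ddg"))
    if (!is.null(raw[[k]]) && !file.exists(raw[[k]]))
      raw[[k]] <- file.path(base_dir, raw[[k]])
  do.call(pipeline_config, raw)
}

#' Run the full scaffold-selection pipeline
#'
#' Executes filter, SASA, conservation, mutability, selection, patch and
#' library stages in order, writing per-stage TSVs, an annotated PDB (patch
#' id in the B-factor column), a patch report, a library design JSON and a
#' run log into \code{config$out_dir}. A failure in any stage propagates
#' with the stage name; outputs of earlier stages remain on disk.
#'
#' @param config A \code{PipelineConfig}.
#' @return Invisibly, a \code{scaffpatch_run} bundle: \code{model},
#'   \code{verdict}, \code{profiles}, \code{mutable}, \code{patches}
#'   (completed), \code{independence}, \code{library}, \code{cassette},
#'   \code{log} (data frame of stage counts), \code{paths}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  note <- function(stage, n, detail = "") {
    log[[length(log) + 1L]] <<- data.frame(stage = stage, count = n,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  paths <- list()

  model <- run_stage("read_structure", read_structure(config$structure))
  chain <- config$chain %||% residue_table(model)$chain[1]
  note("read_structure", nrow(residue_table(model)), model$entry_id)

  verdict <- run_stage("candidate_filter", candidate_filter(model))
  note("candidate_filter", as.integer(verdict$passed),
       paste(verdict$reasons, collapse = ","))

  rsasa <- run_stage("sasa", {
    atom_sasa <- compute_sasa(model, probe_radius = config$probe_radius,
                              n_points = config$n_points)
    relative_sasa(model, residue_sasa(model, atom_sasa),
                  threshold = config$rsasa_threshold)
  })
  note("sasa", sum(rsasa$surface), "surface residues")

  cons_map <- NULL
  if (!is.null(config$msa)) {
    cons_map <- run_stage("conservation", {
      aln <- dedupe(read_alignment(config$msa, ref_id = config$ref_id))
      map_to_structure(column_conservation(aln), model, chain = chain)
    })
    note("conservation", length(cons_map), "residues scored")
  }

  ddg <- run_stage("mutability",
    if (config$use_surrogate) surrogate_ddg(model, rsasa)
    else read_positionscan(config$ddg))
  mut_prof <- mutability_profile(ddg, threshold = config$ddg_threshold)
  note("mutability", nrow(mut_prof), paste("source:", ddg$source))

  profiles <- residue_profiles(rsasa, cons_map, mut_prof)
  mutable <- run_stage("select", {
    if (is.null(cons_map)) {
      # no MSA: disable the conservation gate, keep the others
      pr <- profiles; pr$conservation <- 0
      select_mutable(pr, cons_max = config$cons_max,
                     mut_min = config$mut_min)
    } else {
      select_mutable(profiles, cons_max = config$cons_max,
                     mut_min = config$mut_min)
    }
  })
  note("select", length(mutable),
       paste0(length(attr(mutable, "diagnostics")), " missing scores"))

  patches <- run_stage("patches", {
    graph <- build_contact_graph(model, mutable,
                                 cutoff = config$contact_cutoff)
    seeds <- find_patches(graph, profiles)
    lapply(seeds, complete_patch, model = model, profiles = profiles,
           target_min = config$patch_min, target_max = config$patch_max,
           cutoff = config$contact_cutoff)
  })
  note("patches", length(patches),
       paste(vapply(patches, function(p) p$size, 0L), collapse = ","))

  independence <- NULL
  if (length(patches) >= 2L)
    independence <- run_stage("independence",
      patch_independence(patches, model,
                         min_separation = config$contact_cutoff))

  library <- cassette <- NULL
  if (config$design_library && length(patches)) {
    library <- run_stage("libdesign", {
      top <- patches[[1]]
      rt <- residue_table(model)
      rt <- rt[rt$chain == chain, , drop = FALSE]
      pos <- match(c(top$seed_members, top$completion_members), rt$key)
      library_design(structure_sequence(model, chain), sort(pos),
                     codon = config$codon)
    })
    cassette <- run_stage("cassette", assemble_cassette(library))
    note("libdesign", length(library$randomized_positions),
         library$diversity$protein_diversity_exact)
  }

  log_df <- do.call(rbind, log)
  paths <- write_run_outputs(config, model, verdict, profiles, mutable,
                             patches, independence, library, cassette, log_df)
  invisible(structure(list(model = model, verdict = verdict,
                           profiles = profiles, mutable = mutable,
                           patches = patches, independence = independence,
                           library = library, cassette = cassette,
                           log = log_df, paths = paths, config = config),
                      class = "scaffpatch_run"))
}

#' @keywords internal
write_run_outputs <- function(config, model, verdict, profiles, mutable,
                              patches, independence, library, cassette,
                              log_df) {
  od <- config$out_dir
  p <- list(profiles = file.path(od, "profiles.tsv"),
            patches = file.path(od, "patches.tsv"),
            annotated = file.path(od, "patches.pdb"),
            log = file.path(od, "run_log.tsv"))
  utils::write.table(profiles, p$profiles, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(patch_report(patches), p$patches, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(patches)) {
    member_scores <- unlist(lapply(seq_along(patches), function(i)
      stats::setNames(rep(i, patches[[i]]$size),
                      c(patches[[i]]$seed_members,
                        patches[[i]]$completion_members))))
    write_annotated_structure(model, member_scores, p$annotated)
    sel <- vapply(patches, function(pp)
      paste(key_parts(c(pp$seed_members, pp$completion_members))$seq_num,
            collapse = "+"), "")
    p$selection <- file.path(od, "patches_selection.txt")
    writeLines(sprintf("patch %d: select resi %s", seq_along(patches), sel),
               p$selection)
  }
  if (!is.null(independence)) {
    p$independence <- file.path(od, "patch_independence.tsv")
    utils::write.table(independence, p$independence, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(library)) {
    p$library <- file.path(od, "library.json")
    jsonlite::write_json(list(
      scaffold_protein = library$scaffold_protein,
      randomized_positions = library$randomized_positions,
      codon_per_position = library$codon_per_position,
      diversity = library$diversity), p$library,
      auto_unbox = TRUE, digits = NA)
    p$cassette = file.path(od, "cassette.txt")
    writeLines(c(format_cassette_annotation(cassette), "ORIGIN",
                 cassette$library_dna), p$cassette)
  }
  meta <- data.frame(stage = "parameters", count = NA_integer_,
                     detail = paste0(
                       "version=", as.character(utils::packageVersion("scaffpatch")),
                       "; cons_max=", config$cons_max,
                       "; mut_min=", config$mut_min,
                       "; ddg_threshold=", config$ddg_threshold,
                       "; rsasa_threshold=", config$rsasa_threshold,
                       "; contact_cutoff=", config$contact_cutoff,
                       "; patch_window=", config$patch_min, "-",
                       config$patch_max,
                       "; codon=", config$codon,
                       "; seed=", config$seed))
  utils::write.table(rbind(log_df, meta), p$log, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p
}

#' @export
print.scaffpatch_run <- function(x, ...) {
  cat("Scaffold selection run:", x$model$entry_id, "\n")
  cat(sprintf("  candidate filter: %s\n",
              if (x$verdict$passed) "passed"
              else paste("failed:", paste(x$verdict$reasons, collapse = ", "))))
  cat(sprintf("  %d residues | %d surface | %d mutable | %d patch(es)\n",
              nrow(x$profiles), sum(x$profiles$surface), length(x$mutable),
              length(x$patches)))
  if (length(x$patches)) {
    top <- x$patches[[1]]
    cat(sprintf("  top patch: %d residues (mean mutability %.1f%%)\n",
                top$size, top$mean_mutability))
  }
  if (!is.null(x$library))
    cat(sprintf("  library: %d x %s, stop-free protein diversity %s\n",
                length(x$library$randomized_positions),
                x$library$codon_per_position[1],
                x$library$diversity$protein_diversity_exact))
  cat("  outputs in", x$config$out_dir, "\n")
  invisible(x)
}
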