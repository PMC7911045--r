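test_that("contact graph edges follow the distance cutoff", {
  m2 <- point_model(rbind(c(0, 0, 0), c(5, 0, 0)))
  g <- build_contact_graph(m2, c("A:1", "A:2"))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$dist, 5)

  far <- point_model(rbind(c(0, 0, 0), c(12, 0, 0)))
  expect_equal(nrow(build_contact_graph(far, c("A:1", "A:2"))$edges), 0L)

  tri <- point_model(rbind(c(0, 0, 0), c(6, 0, 0), c(3, 3 * sqrt(3), 0)))
  expect_equal(nrow(build_contact_graph(tri, sprintf("A:%d", 1:3))$edges), 3L)
})

test_that("C-beta is the representative, falling back to C-alpha for Gly", {
  m <- synthetic_structure(6, seed = 1)
  pts <- representative_points(m, "A:1")
  cb <- m$atoms[m$atoms$key == "A:1" & m$atoms$elety == "CB", ]
  expect_equal(unname(pts[1, ]), c(cb$x, cb$y, cb$z))
  gly <- point_model(rbind(c(0, 0, 0)), aa = "G")   # CA only
  expect_equal(unname(representative_points(gly, "A:1")[1, ]), c(0, 0, 0))
  noca <- gly; noca$atoms$elety <- "N"
  expect_error(representative_points(noca, "A:1"), "neither CB nor CA")
})

test_that("patches are the connected components, ordered and flagged", {
  coords <- rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0),   # component of 3
                  c(50, 0, 0))                           # singleton
  m <- point_model(coords)
  g <- build_contact_graph(m, sprintf("A:%d", 1:4))
  ps <- find_patches(g)
  expect_equal(length(ps), 2L)
  expect_equal(vapply(ps, function(p) p$size, 0L), c(3L, 1L))
  expect_true("singleton" %in% ps[[2]]$flags)
  expect_equal(find_patches(build_contact_graph(m, character(0))), list())
})

test_that("components match brute-force reachability on random graphs", {
  set.seed(123)
  for (rep in 1:30) {
    n <- sample(4:10, 1)
    coords <- matrix(stats::runif(n * 3, 0, 15), n, 3)
    m <- point_model(coords)
    keys <- sprintf("A:%d", 1:n)
    cutoff <- stats::runif(1, 4, 10)
    ps <- find_patches(build_contact_graph(m, keys, cutoff))
    # oracle: transitive closure of the adjacency matrix
    adj <- as.matrix(stats::dist(coords)) <= cutoff
    reach <- adj
    for (k in 1:n) reach <- reach | (reach %*% reach > 0)
    oracle <- unname(split(keys, match(apply(reach, 1, paste, collapse = ""),
                                       unique(apply(reach, 1, paste,
                                                    collapse = "")))))
    got <- lapply(ps, function(p) sort(p$seed_members))
    expect_setequal(lapply(oracle, sort), got)
    # partition: every node in exactly one patch
    expect_setequal(unlist(got), keys)
  }
})

# 8 clustered seeds plus candidate neighbours at controlled distances
completion_setup <- function() {
  seeds <- cbind(seq(0, 21, by = 3), 0, 0)               # A:1..A:8
  near <- rbind(c(24, 0, 0), c(27, 0, 0), c(-3, 0, 0))   # A:9, A:10, A:11
  far <- cbind(c(100, 110), 0, 0)                        # A:12, A:13
  m <- point_model(rbind(seeds, near, far))
  prof <- make_profiles(sprintf("A:%d", 1:13),
                        mutability = c(rep(80, 8), 45, 40, 30, 99, 99),
                        conservation = 50)
  g <- build_contact_graph(m, sprintf("A:%d", 1:8))
  list(model = m, prof = prof, patch = find_patches(g, prof)[[1]])
}

test_that("undersized patches are completed greedily by mutability", {
  s <- completion_setup()
  done <- complete_patch(s$patch, s$model, s$prof)
  expect_equal(done$size, 10L)
  expect_setequal(done$seed_members, sprintf("A:%d", 1:8))
  # the two highest-mutability in-range neighbours join, in score order
  expect_equal(done$completion_members, c("A:9", "A:10"))
  expect_false(any(done$completion_members %in% c("A:12", "A:13")))
  expect_false("undersized" %in% done$flags)
})

test_that("completion respects the window, surface rule and seed set", {
  s <- completion_setup()
  eleven <- find_patches(build_contact_graph(
    point_model(cbind(seq(0, 30, by = 3), 0, 0)), sprintf("A:%d", 1:11)),
    make_profiles(sprintf("A:%d", 1:11), 80))[[1]]
  expect_identical(complete_patch(eleven, point_model(cbind(seq(0, 30, by = 3),
                                                            0, 0)),
                                  make_profiles(sprintf("A:%d", 1:11), 80)),
                   eleven)   # already inside 10-12: unchanged

  # no eligible neighbours -> flagged undersized at its current size
  prof_nosurf <- s$prof
  prof_nosurf$surface[9:13] <- FALSE
  und <- complete_patch(s$patch, s$model, prof_nosurf)
  expect_equal(und$size, 8L)
  expect_true("undersized" %in% und$flags)
  # non-surface residues are never added, seeds never removed
  expect_setequal(und$seed_members, s$patch$seed_members)

  big_m <- point_model(cbind(seq(0, 42, by = 3), 0, 0))
  big <- find_patches(build_contact_graph(big_m, sprintf("A:%d", 1:15)),
                      make_profiles(sprintf("A:%d", 1:15), 80))[[1]]
  over <- complete_patch(big, big_m, make_profiles(sprintf("A:%d", 1:15), 80))
  expect_equal(over$size, 15L)                     # never truncated
  expect_true("oversized" %in% over$flags)
})

test_that("greedy completion matches exhaustive search on small cases", {
  # with distinct mutability scores and all candidates in range, the greedy
  # trace must equal the enumeration of the stated objective
  s <- completion_setup()
  done <- complete_patch(s$patch, s$model, s$prof)
  # oracle: repeatedly take the max-score in-range candidate
  mscore <- stats::setNames(s$prof$mutability, s$prof$key)
  members <- s$patch$seed_members
  picks <- character(0)
  while (length(members) < 10) {
    cand <- setdiff(s$prof$key[s$prof$surface], members)
    d <- as.matrix(stats::dist(representative_points(s$model,
                                                     c(members, cand))))
    inrange <- cand[apply(d[-seq_along(members), seq_along(members),
                            drop = FALSE], 1, min) <= 8]
    best <- inrange[order(-mscore[inrange])][1]
    picks <- c(picks, best); members <- c(members, best)
  }
  expect_identical(done$completion_members, picks)
})

test_that("tie-breaks use conservation then author number, deterministically", {
  seeds <- cbind(seq(0, 21, by = 3), 0, 0)
  near <- rbind(c(-3, 0, 0), c(24, 0, 0))
  m <- point_model(rbind(seeds, near))
  prof <- make_profiles(sprintf("A:%d", 1:10), mutability = c(rep(80, 8), 40, 40),
                        conservation = c(rep(50, 8), 60, 30))
  p <- find_patches(build_contact_graph(m, sprintf("A:%d", 1:8)), prof)[[1]]
  done <- complete_patch(p, m, prof)
  expect_equal(done$completion_members, c("A:10", "A:9"))  # lower conservation first
  prof$conservation[9:10] <- 50
  done2 <- complete_patch(p, m, prof)
  expect_equal(done2$completion_members, c("A:9", "A:10")) # then lower number
  expect_identical(complete_patch(p, m, prof), done2)      # repeatable
})

test_that("patch independence reports disjointness and separation", {
  coords <- rbind(c(0, 0, 0), c(3, 0, 0), c(30, 0, 0), c(33, 0, 0))
  m <- point_model(coords)
  prof <- make_profiles(sprintf("A:%d", 1:4), 80)
  mk <- function(keys) find_patches(build_contact_graph(m, keys), prof)[[1]]
  pA <- mk(c("A:1", "A:2")); pB <- mk(c("A:3", "A:4"))
  rep_far <- patch_independence(list(pA, pB), m)
  expect_true(rep_far$independent)
  expect_true(rep_far$disjoint)
  expect_equal(rep_far$min_dist, 27)

  overlap <- patch_independence(list(mk(c("A:1", "A:2")),
                                     mk(c("A:2", "A:3"))), m)
  expect_false(overlap$disjoint)
  expect_false(overlap$independent)

  close_m <- point_model(rbind(c(0, 0, 0), c(3, 0, 0), c(10, 0, 0),
                               c(13, 0, 0)))
  near7 <- patch_independence(
    list(find_patches(build_contact_graph(close_m, c("A:1", "A:2")),
                      prof)[[1]],
         find_patches(build_contact_graph(close_m, c("A:3", "A:4")),
                      prof)[[1]]), close_m)
  expect_true(near7$disjoint)
  expect_equal(near7$min_dist, 7)
  expect_false(near7$independent)   # 7 A <= default 8 A separation
})
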