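test_that("a straight ribbon rasterizes to its analytic voxel count", {
  geo <- volume_geometry(c(64, 64, 64))
  vs <- generate_fold(rbind(c(10, 20, 0), c(30, 20, 0)), 10, 0, geo)
  # analytic: 20 mm x 10 mm ribbon / 1 mm^2 voxel cross-section = 200
  expect_lt(abs(nrow(vs$voxels) - 200) / 200, 0.10)
  expect_identical(max(brute_components(vs$voxels)), 1L)
})

test_that("degenerate inputs are rejected", {
  geo <- volume_geometry(c(32, 32, 32))
  expect_error(generate_fold(rbind(c(1, 1, 1), c(20, 1, 1)), 0, 0, geo),
               class = "sa_degenerate_input")
  expect_error(generate_fold(rbind(c(5, 5, 5), c(5, 5, 5)), 4, 0, geo),
               class = "sa_degenerate_input")
})

test_that("fold generation is a pure function of the RNG state", {
  geo <- volume_geometry(c(64, 64, 64))
  crv <- rbind(c(10, 30, 2), c(28, 34, 2))
  set.seed(99); a <- generate_fold(crv, 8, 1.5, geo)
  set.seed(99); b <- generate_fold(crv, 8, 1.5, geo)
  expect_identical(a$voxels, b$voxels)
})

test_that("zero variability yields exactly one node per label", {
  cfg <- small_config(seed = 61, folds = 20,
                      variability = list(interruption = 0, small_branch = 0,
                                         long_branch = 0, missing_part = 0,
                                         dropout = 0))
  s <- generate_subject(cfg, 1)
  labs <- vapply(s$graph$nodes, function(n) n$label, character(1))
  expect_identical(length(labs), 20L)
  expect_identical(max(table(labs)), 1L)
  expect_identical(nrow(s$events), 0L)
})

test_that("forced interruption always yields at least two nodes per label", {
  cfg <- small_config(seed = 62, folds = 12,
                      variability = list(interruption = 1, small_branch = 0,
                                         long_branch = 0, missing_part = 0))
  for (i in 1:3) {
    s <- generate_subject(cfg, i)
    labs <- vapply(s$graph$nodes, function(n) n$label, character(1))
    expect_true(all(table(labs) >= 2))
  }
})

test_that("manifest labels agree exactly with graph labels", {
  s <- generate_subject(small_config(seed = 63, folds = 25), 1)
  graph_labs <- vapply(s$graph$nodes, function(n) n$label, character(1))
  expect_identical(unname(graph_labs[as.character(s$labels$node_id)]),
                   s$labels$label)
  expect_identical(sort(as.integer(s$labels$node_id)), node_ids(s$graph))
})

test_that("generated graphs validate cleanly across seeds", {
  for (sd in c(71, 72, 73)) {
    cfg <- small_config(seed = sd, folds = 20)
    s <- generate_subject(cfg, 1)
    expect_identical(nrow(validate_graph(s$graph, cfg$nomenclature)), 0L)
  }
})

test_that("junction edges join touching folds, proximity edges near ones", {
  s <- generate_subject(small_config(seed = 64, folds = 30), 1)
  g <- s$graph
  geo <- graph_geometry(g)
  # verify a sample of edges against direct distance recomputation
  edges <- g$edges[seq_len(min(15, length(g$edges)))]
  for (e in edges) {
    va <- g$nodes[[as.character(e$endpoints[1])]]$voxel_rep$voxels
    vb <- g$nodes[[as.character(e$endpoints[2])]]$voxel_rep$voxels
    cheb <- structatlas:::voxel_set_chebyshev(va, vb, upper = 2)
    if (e$kind == "junction") {
      expect_lte(cheb, 1)
    } else {
      expect_gt(cheb, 1)
      d <- structatlas:::voxel_set_min_distance(va, vb, geo, upper = 10)
      expect_lte(d, 3)
    }
  }
})

test_that("event frequencies converge to configured probabilities", {
  p <- 0.3
  n_subj <- 25; folds <- 20
  cfg <- small_config(seed = 65, n_subjects = n_subj, folds = folds,
                      variability = list(interruption = p, small_branch = 0,
                                         long_branch = 0, missing_part = 0))
  gen <- generate_cohort(cfg)
  ev <- gen$manifest$events
  n_events <- sum(ev$event == "interruption")
  trials <- n_subj * folds
  se <- sqrt(p * (1 - p) / trials)
  expect_lt(abs(n_events / trials - p), 3 * se)
})

test_that("the same seed reproduces a byte-identical cohort on disk", {
  cfg <- small_config(seed = 66, n_subjects = 2, folds = 10)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cfg)$cohort, d1)
  write_cohort(generate_cohort(cfg)$cohort, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
  # and a different seed differs
  d3 <- withr::local_tempdir()
  write_cohort(generate_cohort(small_config(seed = 67, n_subjects = 2,
                                            folds = 10))$cohort, d3)
  same <- vapply(list.files(d1, pattern = "sub-"), function(f)
    identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
              readBin(file.path(d3, f), "raw", file.size(file.path(d3, f)))),
    logical(1))
  expect_false(all(same))
})

test_that("subject substreams do not depend on generation order", {
  cfg <- small_config(seed = 68, n_subjects = 3, folds = 8)
  s2_alone <- generate_subject(cfg, 2)
  gen <- generate_cohort(cfg)
  expect_true(graph_equal(gen$cohort$subjects[["sub-002"]], s2_alone$graph))
})

test_that("an empty cohort generates and serializes", {
  gen <- generate_cohort(small_config(seed = 69, n_subjects = 0))
  expect_length(gen$cohort$subjects, 0)
  expect_identical(nrow(gen$manifest$labels), 0L)
})
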