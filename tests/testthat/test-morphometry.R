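test_that("single-voxel and anisotropic sizes follow voxel volume", {
  geo1 <- volume_geometry(c(10, 10, 10))
  n1 <- structure_node(1L, voxel_rep = voxel_surface_set(rbind(c(1, 1, 1)),
                                                         geo1))
  m1 <- compute_node_measures(n1)
  expect_equal(unname(m1["size"]), 1.0)

  geo2 <- volume_geometry(c(20, 10, 10), c(1, 1, 2))
  line <- cbind(0:9, 1, 1)
  n2 <- structure_node(2L, voxel_rep = voxel_surface_set(line, geo2))
  m2 <- compute_node_measures(n2)
  expect_equal(unname(m2["size"]), 20)       # 10 voxels x 2 mm^3
  expect_error(compute_node_measures(structure_node(3L, mesh = cube_mesh())),
               class = "sa_no_representation")
})

test_that("ribbon measurements match the analytic box dimensions", {
  vs <- ribbon_fold(len = 20, depth = 10)
  m <- compute_node_measures(structure_node(1L, voxel_rep = vs))
  expect_equal(unname(m["size"]), nrow(vs$voxels))   # 1 mm iso: count = mm^3
  expect_lt(abs(m["length"] - 20), 1)
  expect_lt(abs(m["max_depth"] - 10), 1)
  expect_lt(abs(m["mean_depth"] - 10), 1)
})

test_that("halving the voxel size scales size by 1/8 and area by 1/4", {
  idx <- ribbon_fold()$voxels
  geoA <- volume_geometry(c(64, 64, 64), c(1, 1, 1))
  geoB <- volume_geometry(c(64, 64, 64), c(0.5, 0.5, 0.5))
  mA <- compute_node_measures(structure_node(1L, voxel_rep =
    voxel_surface_set(idx, geoA, check = FALSE)))
  mB <- compute_node_measures(structure_node(1L, voxel_rep =
    voxel_surface_set(idx, geoB, check = FALSE)))
  expect_equal(unname(mB["size"] / mA["size"]), 1 / 8)
  expect_equal(unname(mB["surface_area"] / mA["surface_area"]), 1 / 4)
})

test_that("thickness and opening pass through untouched", {
  vs <- ribbon_fold()
  n <- structure_node(1L, voxel_rep = vs,
                      properties = c(thickness = 2.5, opening = 1.25))
  m <- compute_node_measures(n)
  expect_equal(unname(m["thickness"]), 2.5)
  expect_equal(unname(m["opening"]), 1.25)
})

# Independent oracle: naive per-label recomputation with explicit loops.
naive_aggregate <- function(graph) {
  labs <- unique(vapply(graph$nodes, function(n) n$label, character(1)))
  rows <- list()
  for (lab in labs) {
    nodes <- Filter(function(n) n$label == lab, graph$nodes)
    props <- lapply(nodes, compute_node_measures)
    sizes <- vapply(props, function(p) unname(p["size"]), numeric(1))
    for (met in c("size", "surface_area", "length")) {
      tot <- 0
      for (p in props) tot <- tot + unname(p[met])
      rows[[length(rows) + 1]] <- data.frame(
        subject = graph$subject_id, label = lab, metric = met, value = tot)
    }
    for (met in c("max_depth", "mean_depth")) {
      num <- 0
      for (i in seq_along(props)) num <- num + unname(props[[i]][met]) * sizes[i]
      rows[[length(rows) + 1]] <- data.frame(
        subject = graph$subject_id, label = lab, metric = met,
        value = num / sum(sizes))
    }
  }
  do.call(rbind, rows)
}

test_that("additivity: two nodes of one label sum their sizes", {
  geo <- volume_geometry(c(40, 40, 40))
  g <- structural_graph("s")
  g <- add_node(g, structure_node(1L, label = "S",
    voxel_rep = voxel_surface_set(rbind(c(1, 1, 1), c(1, 1, 2), c(1, 2, 2)),
                                  geo)))
  g <- add_node(g, structure_node(2L, label = "S",
    voxel_rep = voxel_surface_set(cbind(5:8, 5, 5), geo)))
  tab <- aggregate_morphometry(g)
  expect_equal(tab$value[tab$metric == "size" & tab$label == "S"], 7)
})

test_that("aggregates equal naive per-label recomputation on generated graphs", {
  for (sd in c(9, 10)) {
    s <- generate_subject(small_config(seed = sd, folds = 30), 1)
    tab <- aggregate_morphometry(s$graph)
    oracle <- naive_aggregate(s$graph)
    key <- function(d) paste(d$label, d$metric)
    expect_setequal(key(tab), key(oracle))
    m <- match(key(oracle), key(tab))
    expect_lt(max(abs(tab$value[m] - oracle$value)), 1e-9)
  }
})

test_that("unlabeled nodes report under the unknown sentinel", {
  g <- ribbon_graph()
  g$nodes[["1"]]$label <- UNKNOWN_LABEL
  tab <- aggregate_morphometry(g)
  expect_true(all(tab$label == UNKNOWN_LABEL))
})

test_that("cohort table concatenates per-subject aggregates", {
  gen <- generate_cohort(small_config(seed = 12, n_subjects = 3, folds = 12))
  tab <- cohort_morphometry(gen$cohort)
  expect_setequal(unique(tab$subject), names(gen$cohort$subjects))
  for (sid in names(gen$cohort$subjects)) {
    sub <- tab[tab$subject == sid, ]
    single <- aggregate_morphometry(gen$cohort$subjects[[sid]],
                                    gen$cohort$nomenclature)
    expect_identical(nrow(sub), nrow(single))
    expect_lt(max(abs(sort(sub$value) - sort(single$value))), 1e-9)
  }
  # no duplicate (subject, label, metric) triple
  expect_false(any(duplicated(tab[c("subject", "label", "metric")])))
  # empty cohort -> empty table
  expect_identical(nrow(cohort_morphometry(cohort(list()))), 0L)
})

test_that("identical subjects yield identical per-label rows", {
  g <- ribbon_graph()
  g2 <- g; g2$subject_id <- "rib2"
  tab <- cohort_morphometry(cohort(list(g, g2)))
  a <- tab[tab$subject == "rib", ]
  b <- tab[tab$subject == "rib2", ]
  expect_identical(a$value, b$value)
})

test_that("morphometry CSV round-trips with fixed column order", {
  s <- generate_subject(small_config(seed = 13, folds = 10), 1)
  tab <- aggregate_morphometry(s$graph)
  f <- withr::local_tempfile(fileext = ".csv")
  write_morphometry_csv(tab, f)
  expect_identical(readLines(f, n = 1), "subject,label,metric,value")
  back <- read_morphometry_csv(f)
  expect_identical(back$label, tab$label)
  expect_lt(max(abs(back$value - tab$value)), 1e-12)
})
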