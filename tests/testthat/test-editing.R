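label_nom <- function() {
  nomenclature(nomenclature_entry("brain", children = list(
    nomenclature_entry("S.C."), nomenclature_entry("S.F.sup."),
    nomenclature_entry("S.Fr.1"))))
}

three_node_graph <- function() {
  g <- structural_graph("sA")
  geo <- volume_geometry(c(40, 40, 40))
  for (i in 1:3)
    g <- add_node(g, structure_node(i, voxel_rep = voxel_surface_set(
      rbind(c(10 * i, 10, 10)), geo, check = FALSE)))
  g
}

test_that("pasting a label touches exactly the listed nodes", {
  g <- three_node_graph()
  nom <- label_nom()
  g2 <- set_label(g, c(1, 3), "S.F.sup.", nom)
  expect_identical(g2$nodes[["1"]]$label, "S.F.sup.")
  expect_identical(g2$nodes[["2"]]$label, UNKNOWN_LABEL)
  expect_identical(g2$nodes[["3"]]$label, "S.F.sup.")
  expect_error(set_label(g, 1, "not.in.nom", nom),
               class = "sa_label_not_in_nomenclature")
  expect_error(set_label(g, 9, "S.C.", nom), class = "sa_not_found")
  # the unknown sentinel is always pastable (clears the annotation)
  expect_silent(set_label(g2, 1, UNKNOWN_LABEL, nom))
})

test_that("copy/paste carries a label across subjects", {
  gA <- set_label(three_node_graph(), 2, "S.C.", label_nom())
  gB <- three_node_graph()
  gB$subject_id <- "sB"
  clip <- copy_label(gA, 2)
  expect_identical(clip$label, "S.C.")
  expect_identical(clip$source_subject, "sA")
  gB2 <- paste_label(gB, c(1, 2), clip, label_nom())
  expect_identical(gB2$nodes[["1"]]$label, "S.C.")
  expect_identical(gB2$nodes[["2"]]$label, "S.C.")
  expect_error(copy_label(gB, 1), class = "sa_unlabeled_source")
  expect_error(copy_label(gA, 77), class = "sa_not_found")
})

test_that("relabeling moves exactly one node's contribution between sulci", {
  s <- generate_subject(small_config(seed = 5), 1)
  g <- s$graph
  nom <- small_config(seed = 5)$nomenclature
  labs <- vapply(g$nodes, function(n) n$label, character(1))
  from <- names(which(table(labs) >= 2))[1]
  to <- setdiff(unique(labs), from)[1]
  victim <- as.integer(names(labs)[labs == from][1])
  before <- aggregate_morphometry(g, nom)
  after <- aggregate_morphometry(set_label(g, victim, to, nom), nom)
  moved <- compute_node_measures(g$nodes[[as.character(victim)]])
  pick <- function(tab, lab, met) {
    r <- tab$value[tab$label == lab & tab$metric == met]
    if (length(r) == 0) 0 else r
  }
  for (met in c("size", "length", "surface_area")) {
    expect_equal(pick(after, from, met),
                 pick(before, from, met) - unname(moved[met]), tolerance = 1e-9)
    expect_equal(pick(after, to, met),
                 pick(before, to, met) + unname(moved[met]), tolerance = 1e-9)
  }
})

test_that("splitting a ribbon partitions it into two connected children", {
  g <- ribbon_graph()           # 20 x 10 x 1 ribbon, 200 voxels
  parent <- g$nodes[["1"]]$voxel_rep$voxels
  res <- split_node(g, 1, c(20, 20, 5))   # mid-ribbon seed (mm)
  expect_identical(sort(res$new_ids), c(2L, 3L))
  expect_length(res$graph$nodes, 1 + length(g$nodes))  # 1 -> 2 nodes
  v1 <- res$graph$nodes[[as.character(res$new_ids[1])]]$voxel_rep$voxels
  v2 <- res$graph$nodes[[as.character(res$new_ids[2])]]$voxel_rep$voxels
  # exact partition of the parent set
  expect_identical(nrow(v1) + nrow(v2), nrow(parent))
  both <- rbind(v1, v2)
  expect_identical(nrow(unique(both)), nrow(parent))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_setequal(key(both), key(parent))
  # both children connected (independent sweep-based oracle)
  expect_identical(max(brute_components(v1)), 1L)
  expect_identical(max(brute_components(v2)), 1L)
  # junction edge between the children
  ek <- vapply(res$graph$edges, function(e)
    e$kind == "junction" && setequal(e$endpoints, res$new_ids), logical(1))
  expect_true(any(ek))
  expect_identical(nrow(validate_graph(res$graph)), 0L)
  # children inherit the parent label
  expect_identical(res$graph$nodes[[as.character(res$new_ids[1])]]$label,
                   "S.Fr.1")
})

test_that("split component sizes match brute-force recount after spine removal", {
  g <- ribbon_graph()
  v <- g$nodes[["1"]]$voxel_rep$voxels
  res <- split_node(g, 1, c(20, 20, 5))
  # oracle: remove the same cut column and recount by sweeps
  spine_col <- v[, 1] == 20
  comp <- brute_components(v[!spine_col, , drop = FALSE])
  oracle_sizes <- sort(as.integer(table(comp)))
  sizes <- sort(vapply(res$new_ids, function(id)
    nrow(res$graph$nodes[[as.character(id)]]$voxel_rep$voxels), integer(1)))
  # children also absorbed the spine voxels; subtract them
  expect_identical(sum(sizes), nrow(v))
  expect_identical(sum(oracle_sizes), nrow(v) - sum(spine_col))
  expect_identical(max(brute_components(v[spine_col, , drop = FALSE])), 1L)
})

test_that("off-structure seeds and ineffective cuts are rejected", {
  g <- ribbon_graph()
  expect_error(split_node(g, 1, c(60, 60, 60)),
               class = "sa_seed_off_structure")
  expect_error(split_node(g, 99, c(20, 20, 5)), class = "sa_not_found")
  # a 3D blob cannot be severed by a 1-voxel-wide spine: ineffective
  geo <- volume_geometry(c(30, 30, 30))
  blob <- as.matrix(expand.grid(5:14, 5:14, 5:14))
  gb <- structural_graph("blob")
  gb <- add_node(gb, structure_node(1L, voxel_rep = voxel_surface_set(
    blob, geo, check = FALSE)))
  expect_error(split_node(gb, 1, c(10, 10, 10)),
               class = "sa_cut_ineffective")
})

test_that("edges re-home to the child nearest the former neighbour", {
  g <- ribbon_graph()
  geo <- graph_geometry(g)
  # neighbour fold near the ribbon's left end (low x)
  left <- generate_fold(rbind(c(8, 22, 0), c(12, 22, 0)), 6, 0, geo)
  g <- add_node(g, structure_node(2L, voxel_rep = left))
  g <- add_edge(g, structure_edge(1L, "proximity", c(1L, 2L)))
  res <- split_node(g, 1, c(20, 20, 5))
  # children: one covers x in [10,19], the other x in [21,30] (plus spine)
  xr <- vapply(res$new_ids, function(id)
    min(res$graph$nodes[[as.character(id)]]$voxel_rep$voxels[, 1]),
    numeric(1))
  left_child <- res$new_ids[which.min(xr)]
  rehomed <- Filter(function(e) 2L %in% e$endpoints, res$graph$edges)
  expect_length(rehomed, 1)
  expect_setequal(rehomed[[1]]$endpoints, c(left_child, 2L))
})

test_that("split followed by merge restores the voxel set exactly", {
  g <- ribbon_graph()
  before <- g$nodes[["1"]]$voxel_rep$voxels
  res <- split_node(g, 1, c(20, 20, 5))
  merged <- merge_nodes(res$graph, res$new_ids[1], res$new_ids[2])
  after <- merged$nodes[[as.character(res$new_ids[1])]]$voxel_rep$voxels
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_setequal(key(after), key(before))
  expect_identical(nrow(validate_graph(merged)), 0L)
  # the junction edge between the children is gone
  expect_length(Filter(function(e)
    all(res$new_ids %in% e$endpoints), merged$edges), 0)
})

test_that("merging keeps the first label and the union voxel count", {
  geo <- volume_geometry(c(40, 40, 40))
  a <- generate_fold(rbind(c(5, 10, 0), c(15, 10, 0)), 5, 0, geo)
  b <- generate_fold(rbind(c(16, 10, 0), c(24, 10, 0)), 5, 0, geo)
  g <- structural_graph("m")
  g <- add_node(g, structure_node(1L, label = "S.Fr.1", voxel_rep = a))
  g <- add_node(g, structure_node(2L, label = "S.Fr.2", voxel_rep = b))
  m <- merge_nodes(g, 1, 2)
  expect_identical(m$nodes[["1"]]$label, "S.Fr.1")
  expect_identical(nrow(m$nodes[["1"]]$voxel_rep$voxels),
                   nrow(a$voxels) + nrow(b$voxels))
  expect_error(merge_nodes(g, 1, 9), class = "sa_not_found")
})

test_that("random cuts on generated folds conserve voxels and connectivity", {
  set.seed(55)
  geo <- volume_geometry(c(72, 72, 72))
  done <- 0
  for (rep in 1:12) {
    L <- runif(1, 14, 22); D <- runif(1, 7, 11)
    th <- runif(1, 0, pi)
    u <- c(cos(th), sin(th), 0)
    ctr <- runif(3, 25, 45)
    crv <- rbind(ctr - u * L / 2, ctr + u * L / 2)
    vs <- generate_fold(crv, D, jitter = 1, geometry = geo)
    g <- structural_graph("rc")
    g <- add_node(g, structure_node(1L, label = "S.Fr.1", voxel_rep = vs))
    seed_mm <- ctr + c(0, 0, D / 2)
    res <- tryCatch(split_node(g, 1, seed_mm),
                    structatlas_error = function(e) NULL)
    if (is.null(res)) next   # cut through this random fold was ineffective
    done <- done + 1
    v1 <- res$graph$nodes[[as.character(res$new_ids[1])]]$voxel_rep$voxels
    v2 <- res$graph$nodes[[as.character(res$new_ids[2])]]$voxel_rep$voxels
    expect_identical(nrow(v1) + nrow(v2), nrow(vs$voxels))
    expect_identical(nrow(unique(rbind(v1, v2))), nrow(vs$voxels))
    expect_identical(nrow(validate_graph(res$graph)), 0L)
    merged <- merge_nodes(res$graph, res$new_ids[1], res$new_ids[2])
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    expect_setequal(key(merged$nodes[[1]]$voxel_rep$voxels), key(vs$voxels))
  }
  expect_gte(done, 8)
})
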