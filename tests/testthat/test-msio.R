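test_that("peak tables are read sorted, deduplicated, with delimiter/header autodetection", {
  p <- write_lines_tmp(c("500.1,10", "300.2,5"))
  pl <- read_peaklist_table(p, "A", "r1")
  expect_s3_class(pl, "peaklist")
  expect_equal(pl$peaks$mz, c(300.2, 500.1))
  expect_equal(pl$peaks$intensity, c(5, 10))

  # duplicate mz collapses to max intensity
  p <- write_lines_tmp(c("300.2,5", "300.2,7"))
  pl <- read_peaklist_table(p, "A")
  expect_equal(nrow(pl$peaks), 1L)
  expect_equal(pl$peaks$intensity, 7)

  # header row, semicolon dialect, extra columns ignored
  p <- write_lines_tmp(c("mass;area;snr;flag", "1200.5;3;9;x", "900.1;2;4;y"))
  pl <- read_peaklist_table(p, "B")
  expect_equal(pl$peaks$mz, c(900.1, 1200.5))

  # tab dialect
  p <- write_lines_tmp(c("400\t1", "500\t2"))
  expect_equal(read_peaklist_table(p, "C")$peaks$mz, c(400, 500))
})

test_that("malformed and empty peak tables fail with informative errors", {
  p <- write_lines_tmp(c("abc,5"))
  expect_error(read_peaklist_table(p, "A"), "line 1")
  p <- write_lines_tmp(c("mz,intensity", "100,2", "oops,3"))
  expect_error(read_peaklist_table(p, "A"), "line 3")
  p <- write_lines_tmp(character(0))
  expect_error(read_peaklist_table(p, "A"), "no peaks")
  p <- write_lines_tmp(c("mz,intensity"))
  expect_error(read_peaklist_table(p, "A"), "no peaks")
})

test_that("peak table write/read round-trips to 6 significant digits", {
  set.seed(42)
  pl <- peaklist(sort(runif(50, 200, 15000)), rexp(50, 1 / 100),
                 isolate_id = "RT", replicate_id = "r1")
  path <- tempfile(fileext = ".tsv")
  write_peaklist_table(pl, path)
  back <- read_peaklist_table(path, "RT", "r1")
  expect_equal(signif(back$peaks$mz, 6), signif(pl$peaks$mz, 6))
  expect_equal(signif(back$peaks$intensity, 6),
               signif(pl$peaks$intensity, 6))
})

test_that("mzML reading assigns isolate/replicate ids via the naming pattern", {
  pls <- lapply(1:3, function(r)
    peaklist(c(300.5, 1000 + r), c(5, 10), isolate_id = "A",
             replicate_id = paste0("r", r)))
  path <- tempfile(fileext = ".mzML")
  strainpick:::write_mzml(pls, path)
  got <- read_mzml(path)
  expect_length(got, 3L)
  expect_true(all(vapply(got, `[[`, "", "isolate_id") == "A"))
  expect_equal(vapply(got, `[[`, "", "replicate_id"), c("r1", "r2", "r3"))
  expect_equal(got[[2]]$peaks$mz, pls[[2]]$peaks$mz)

  # pattern mismatch names the offending spectrum ids
  expect_error(read_mzml(path, pattern = "{isolate}-{replicate}"), "A_r1")
})

test_that("mzML degenerate inputs behave per contract", {
  empty <- tempfile(fileext = ".mzML")
  strainpick:::write_mzml(list(), empty)
  expect_warning(got <- read_mzml(empty), "no spectra")
  expect_length(got, 0L)

  prof <- tempfile(fileext = ".mzML")
  strainpick:::write_mzml(list(peaklist(c(300, 301, 302), c(1, 5, 1),
                                        isolate_id = "A",
                                        replicate_id = "r1")),
                          prof, centroided = FALSE)
  expect_error(read_mzml(prof), "profile spectra not supported")
  expect_length(read_mzml(prof, force_centroid = TRUE), 1L)

  expect_error(read_mzml(write_lines_tmp("not xml", ".mzML")),
               "invalid mzML")
})

test_that("Newick export uses merge-height branch lengths and round-trips", {
  hc <- list(merge = matrix(c(-1, -2), 1), height = 0.4, order = 1:2,
             labels = c("A", "B"), method = "average")
  class(hc) <- "hclust"
  expect_equal(as.character(write_newick(hc)), "(A:0.4,B:0.4);")
  expect_equal(as.character(write_newick("A")), "A;")

  # 3-leaf tree with known merges, reparsed by an independent parser
  d <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc3 <- build_dendrogram(d, "average")
  path <- tempfile(fileext = ".nwk")
  write_newick(hc3, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, c("A", "B", "C"))
  # topology: A and B are siblings
  mrca_ab <- ape::getMRCA(tree, c("A", "B"))
  expect_false(mrca_ab == ape::getMRCA(tree, c("A", "C")))
  # ultrametric with tip depth equal to the root merge height
  depths <- ape::node.depth.edgelength(tree)
  expect_equal(unname(depths[1:3]), rep(0.9, 3), tolerance = 1e-9)
  # A-B divergence at the first merge height
  d_ab <- ape::cophenetic.phylo(tree)["A", "B"]
  expect_equal(unname(d_ab), 2 * 0.1, tolerance = 1e-9)
})

test_that("GraphML export encodes node roles and round-trips the adjacency", {
  fm <- fm_from_sets(list(A = c(1, 2), B = c(2, 3)))
  man <- build_man(c("A", "B"), fm, group_id = 1L)
  path <- tempfile(fileext = ".graphml")
  write_graphml(man, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 5L)  # 2 isolates + 3 features
  expect_equal(igraph::ecount(g), 4L)
  expect_setequal(igraph::V(g)$node_type,
                  c("isolate", "isolate", "feature", "feature", "feature"))
  # adjacency identical to the MAN's edge set
  el <- igraph::as_edgelist(g)
  got <- sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  want <- sort(paste(man$edges$isolate_id,
                     paste0("feature_", man$edges$feature_id)))
  expect_equal(got, want)
  # unannotated flags are "na"
  expect_true(all(igraph::V(g)$selected[igraph::V(g)$node_type ==
                                          "isolate"] == "na"))

  # annotation is carried into attributes
  sel <- prioritize_group(c("A", "B"), fm, threshold = 0.6, group_id = 1L)
  write_graphml(annotate_man(man, sel), path)
  g2 <- igraph::read_graph(path, format = "graphml")
  caps <- igraph::V(g2)$captured[igraph::V(g2)$node_type == "feature"]
  expect_setequal(unique(caps), c("true", "false"))
})

test_that("an empty MAN writes valid GraphML with zero nodes", {
  man <- structure(list(group_id = 1L, isolates = character(0),
                        features = integer(0),
                        edges = data.frame(isolate_id = character(0),
                                           feature_id = integer(0)),
                        selected = NULL, captured = NULL),
                   class = "man")
  path <- tempfile(fileext = ".graphml")
  write_graphml(man, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 0L)
})
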