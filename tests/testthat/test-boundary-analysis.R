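test_that("assign_rows layers a hand-built adjacency correctly", {
  adj <- data.frame(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5))
  r <- assign_rows(adj, source = 1, max_row = 2)
  expect_equal(r$row[match(1:5, r$cell)], c(NA, 0L, 1L, 2L, NA))
  expect_equal(r$source, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_error(assign_rows(adj, source = integer(0)), "empty")
  expect_error(assign_rows(adj, source = 99), "unknown")
  expect_error(assign_rows(adj, source = 1:5), "covers all")
})

test_that("assign_rows matches the igraph breadth-first oracle", {
  tis <- generate_tissue(tissue_spec(n_cols = 10, n_rows = 10,
                                     cell_diameter = 18, jitter = 0.2,
                                     seed = 14))
  g <- parse_tissue(tis$labels)
  src <- boundary_source_cells(tis, 2)
  got <- assign_rows(g, src, max_row = 3)
  oracle <- igraph_row_oracle(g, src, max_row = 3)
  expect_equal(got$row, oracle$row)
  expect_equal(got$source, oracle$source)
})

test_that("the 45-degree junction class rule is exact at the boundary", {
  expect_equal(classify_junction_angle(c(44.9, 45, 45.1), 0),
               c("horizontal", "horizontal", "medio-lateral"))
  expect_equal(classify_junction_angle(0, 0), "horizontal")
  expect_equal(classify_junction_angle(90, 0), "medio-lateral")
  # relative to a tilted boundary axis
  expect_equal(classify_junction_angle(80, 60), "horizontal")
  expect_equal(classify_junction_angle(120, 60), "medio-lateral")
})

test_that("classify_junctions assigns rows, boundaries and classes", {
  tis <- generate_tissue(tissue_spec(n_cols = 8, n_rows = 8,
                                     cell_diameter = 20, jitter = 0.1,
                                     seed = 15))
  g <- parse_tissue(tis$labels)
  src <- boundary_source_cells(tis, 2)
  asg <- assign_rows(g, src, max_row = 3)
  cls <- classify_junctions(g, asg, boundary_axis = 0)
  expect_true(all(cls$class[!cls$unclassified] %in%
                    c("horizontal", "medio-lateral")))
  expect_true(all(cls$angle_to_boundary >= 0 & cls$angle_to_boundary <= 90,
                  na.rm = TRUE))
  # boundary-0 junctions link a source cell and a row-0 cell
  b0 <- cls[!is.na(cls$boundary) & cls$boundary == 0, ]
  expect_gt(nrow(b0), 0)
  m <- function(cells) asg$source[match(cells, asg$cell)]
  expect_true(all(xor(m(b0$cell_a), m(b0$cell_b))))
  # a shared-row junction has both cells in that row
  r1 <- cls[!is.na(cls$row) & cls$row == 1, ][1, ]
  rows_of <- asg$row[match(c(r1$cell_a, r1$cell_b), asg$cell)]
  expect_equal(rows_of, c(1L, 1L))
})

test_that("summarize_junction_intensity averages per class and row", {
  tis <- generate_tissue(tissue_spec(n_cols = 8, n_rows = 8,
                                     cell_diameter = 20, jitter = 0.1,
                                     seed = 15))
  g <- parse_tissue(tis$labels)
  src <- boundary_source_cells(tis, 2)
  asg <- assign_rows(g, src, max_row = 3)
  cls <- classify_junctions(g, asg, boundary_axis = 0)
  chan <- matrix(7, nrow(tis$labels), ncol(tis$labels)) # constant channel
  s <- summarize_junction_intensity(g, cls, chan, background = 2)
  expect_true(all(abs(s$junctions$mean_intensity - 5) < 1e-10))
  expect_true(all(abs(s$by_class$mean_intensity - 5) < 1e-10))
  expect_true(all(abs(s$by_row$mean_intensity - 5) < 1e-10))
  expect_equal(sum(s$by_class$n), sum(!is.na(s$junctions$class) &
                                        is.finite(s$junctions$mean_intensity)))
})
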