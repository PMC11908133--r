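test_that("gene category assignment covers the full panel", {
  expect_equal(assign_gene_category("DNMT3A"), "ER")
  expect_equal(assign_gene_category("U2AF1"), "RS")
  expect_equal(assign_gene_category("JAK2"), "ST")
  expect_equal(assign_gene_category("RUNX1"), "TF")
  expect_equal(assign_gene_category("STAG2"), "CS")
  expect_equal(assign_gene_category("FAKE1"), "uncategorized")
  tab <- gene_category_table()
  expect_false(anyDuplicated(tab$gene) > 0)
  expect_true(all(assign_gene_category(tab$gene) != "uncategorized"))
  expect_setequal(unique(tab$category), c("ER", "RS", "ST", "TF", "CS"))
})

mk_netfit <- function(blocks, s_per_clone, pid) {
  vt <- do.call(rbind, lapply(seq_along(blocks), function(b)
    data.frame(variant = blocks[[b]], clone = b, s = s_per_clone[b],
               atma = 40, atma_flag = NA, macs120 = NA, log_macs120 = NA,
               lead = seq_along(blocks[[b]]) == 1)))
  structure(list(variants = vt, structure = blocks,
                 clones = lapply(seq_along(blocks), function(b)
                   list(variants = blocks[[b]], map_s = s_per_clone[b],
                        lead = blocks[[b]][1])),
                 params = ch_params(), participant_id = pid),
            class = "ch_fit")
}

test_that("co-occurrence edges count participant-clones containing both labels", {
  fits <- list(
    P1 = mk_netfit(list(c("ASXL1:a", "TET2:t")), 0.2, "P1"),
    P2 = mk_netfit(list(c("ASXL1:a2", "TET2:t2")), 0.15, "P2"),
    P3 = mk_netfit(list("JAK2:j"), 0.3, "P3"))
  net <- build_network(fits, level = "gene")
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$count, 2)
  expect_setequal(c(net$edges$from, net$edges$to), c("ASXL1", "TET2"))
  expect_setequal(net$nodes$label, c("ASXL1", "TET2", "JAK2"))
  expect_equal(net$nodes$count[net$nodes$label == "ASXL1"], 2)
  # brute-force recount of symmetric pair membership
  n_pairs <- sum(vapply(fits, function(f)
    any(vapply(f$structure, function(bl)
      all(c("ASXL1", "TET2") %in% sub(":.*", "", bl)), logical(1))),
    logical(1)))
  expect_equal(net$edges$count, n_pairs)
  # no co-occurrence anywhere -> zero edges
  net0 <- build_network(fits["P3"])
  expect_equal(nrow(net0$edges), 0)
  expect_equal(igraph::vcount(net0$graph), 1)
})

test_that("node colors rescale between min and max log fitness", {
  fits <- list(P1 = mk_netfit(list("A:a"), 0.1, "P1"),
               P2 = mk_netfit(list("B:b"), 0.3, "P2"))
  net <- build_network(fits)
  expect_equal(sort(net$nodes$color), c(0, 1))
  # degenerate rescale: all nodes share one fitness -> 0.5
  fits_eq <- list(P1 = mk_netfit(list("A:a"), 0.2, "P1"),
                  P2 = mk_netfit(list("B:b"), 0.2, "P2"))
  expect_equal(build_network(fits_eq)$nodes$color, c(0.5, 0.5))
})

test_that("network export writes GraphML and JSON", {
  fits <- list(P1 = mk_netfit(list(c("ASXL1:a", "TET2:t")), 0.2, "P1"))
  net <- build_network(fits)
  gml <- withr::local_tempfile(fileext = ".graphml")
  js <- withr::local_tempfile(fileext = ".json")
  export_network(net, graphml = gml, json = js)
  expect_true(file.exists(gml) && file.size(gml) > 0)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(parsed$nodes), 2)
  expect_equal(parsed$edges$count, 2 / 2)  # one participant-clone
})

test_that("Brunner-Munzel agrees with a direct placement-based computation", {
  oracle_bm <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    # placements computed by explicit counting
    F2 <- function(v) sum(y < v) + 0.5 * sum(y == v)
    G1 <- function(v) sum(x < v) + 0.5 * sum(x == v)
    p1 <- vapply(x, F2, numeric(1))  # rank of x_i among y
    p2 <- vapply(y, G1, numeric(1))
    pst <- mean(p2) / n1
    s1 <- stats::var(p1) / n2^2
    s2 <- stats::var(p2) / n1^2
    se <- sqrt(s1 / n1 + s2 / n2)
    stat <- (pst - 0.5) / se
    df <- (s1 / n1 + s2 / n2)^2 /
      ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
    list(statistic = stat, df = df, p = 2 * stats::pt(-abs(stat), df))
  }
  set.seed(401)
  for (i in 1:10) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    got <- brunner_munzel_test(x, y)
    ora <- oracle_bm(x, y)
    expect_equal(got$statistic, ora$statistic, tolerance = 1e-9)
    expect_equal(got$df, ora$df, tolerance = 1e-9)
    expect_equal(got$p.value, ora$p, tolerance = 1e-9)
  }
  # a large constant shift is detected decisively at n = 30
  x <- rnorm(30); y <- rnorm(30) + 5
  expect_lt(brunner_munzel_test(x, y)$p.value, 1e-3)
})

test_that("Brunner-Munzel holds its size under the null", {
  set.seed(402)
  pvals <- replicate(400, {
    z <- rnorm(24)
    brunner_munzel_test(z[1:12], z[13:24])$p.value
  })
  expect_lt(mean(pvals < 0.05), 0.09)
  expect_gt(mean(pvals < 0.05), 0.015)
})

test_that("isolated-vs-co-occurring comparison tests with BY correction", {
  set.seed(403)
  fits <- list()
  # RS-alone clones with high fitness, RS-with-ER co-occurring lower
  for (i in 1:15)
    fits[[paste0("A", i)]] <- mk_netfit(list(sprintf("SF3B1:v%d", i)),
                                        exp(rnorm(1, log(0.3), 0.1)),
                                        paste0("A", i))
  for (i in 1:12)
    fits[[paste0("B", i)]] <- mk_netfit(
      list(c(sprintf("SRSF2:w%d", i), sprintf("DNMT3A:d%d", i))),
      exp(rnorm(1, log(0.08), 0.1)), paste0("B", i))
  res <- compare_isolated_vs_cooccurring(fits, grouping = "category")
  rs <- res[res$group == "RS" & is.na(res$partner), ]
  expect_equal(rs$n_alone, 15)
  expect_equal(rs$n_co, 12)
  expect_gt(rs$mean_log_s_alone, rs$mean_log_s_co)  # alone fitter
  expect_lt(rs$p, 0.01)
  # adjusted p-values dominate raw ones and are monotone
  ok <- !is.na(res$p_adj)
  expect_true(all(res$p_adj[ok] >= res$p[ok]))
  o <- order(res$p[ok])
  expect_true(all(diff(res$p_adj[ok][o]) >= -1e-12))
  # insufficient arms are flagged, not tested
  small <- compare_isolated_vs_cooccurring(fits["A1"], grouping = "gene")
  expect_true(all(small$flag == "insufficient"))
  expect_true(all(is.na(small$p_adj)))
})
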