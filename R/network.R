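# Gene functional categories, co-occurrence network summaries, and the
# isolated-vs-co-occurring fitness comparison.

gene_categories <- list(
  ER = c("DNMT3A", "TET2",                       # DNA methylation
         "ASXL1", "EZH2", "CREBBP", "KDM6A", "PHF6",  # histone modification
         "IDH1", "IDH2"),
  RS = c("SF3B1", "SRSF2",                       # core splicing factors
         "U2AF1", "U2AF2",                       # splice-site recognition
         "ZRSR2", "LUC7L2", "PRPF40B", "SF3A1"),
  ST = c("JAK2", "BRAF", "KRAS", "NRAS", "PPM1D", "PTPN11", "CBL",
         "NOTCH1", "GNAS", "GNB1", "SH2B3", "NF1", "MPL", "PTEN", "CALR"),
  TF = c("TP53", "BCORL1", "WT1", "ZNF318", "CUX1", "CEBPA", "RUNX1",
         "ZBTB33", "ETV6", "GATA2"),
  CS = c("BRCC3", "STAG2", "RAD21", "SMC1A", "SMC3", "CTCF"))

#' Gene functional-category table
#'
#' The five functional groups used throughout: Epigenetic Regulation (ER),
#' RNA Splicing and Processing (RS), Signal Transduction (ST),
#' Transcription Factors (TF) and Chromatin Structure (CS).
#'
#' @return Data.frame with columns `gene` and `category`.
#' @export
gene_category_table <- function() {
  do.call(rbind, lapply(names(gene_categories), function(cat)
    data.frame(gene = gene_categories[[cat]], category = cat,
               stringsAsFactors = FALSE)))
}

#' Assign a gene to its functional category
#'
#' @param gene Character vector of HGNC-style gene symbols.
#' @return Character vector of categories (`"ER"`, `"RS"`, `"ST"`, `"TF"`,
#'   `"CS"`); genes outside the panel map to `"uncategorized"` and are
#'   excluded from category-level analyses.
#' @examples
#' assign_gene_category(c("DNMT3A", "U2AF1", "FAKE1"))
#' @export
assign_gene_category <- function(gene) {
  tab <- gene_category_table()
  cat <- tab$category[match(gene, tab$gene)]
  cat[is.na(cat)] <- "uncategorized"
  cat
}

# Per-variant summary rows across a cohort of fits: label, fitness,
# co-occurrence status and co-partner labels.
variant_rows <- function(fits, level = c("gene", "category"), s_floor) {
  level <- match.arg(level)
  rows <- list()
  for (pid in names(fits)) {
    fit <- fits[[pid]]
    for (b in seq_along(fit$structure)) {
      block <- fit$structure[[b]]
      s <- fit$clones[[b]]$map_s
      genes <- vapply(strsplit(block, ":", fixed = TRUE), `[[`, character(1), 1)
      labs <- if (level == "gene") genes else assign_gene_category(genes)
      for (i in seq_along(block)) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, variant = block[i], label = labs[i],
          log_s = log(max(s, s_floor)), co = length(block) > 1L,
          partners = paste(sort(labs[-i]), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(participant_id = character(0), variant = character(0),
                      label = character(0), log_s = numeric(0),
                      co = logical(0), partners = character(0)))
  do.call(rbind, rows)
}

#' Build a mutation co-occurrence network summary
#'
#' Nodes are genes (or functional categories) of the fitted variants; an
#' edge joins two labels whenever variants carrying them share a clone in
#' any participant. Node attributes: `count` (variant instances), `size`
#' (`log(count)`), `mean_log_s` and `color` (mean log fitness linearly
#' rescaled to `[0, 1]` between the cohort minimum and maximum; 0.5 when
#' they coincide). Edge attributes: `count` (participant-clones containing
#' both labels) and `mean_log_s` of the two endpoints.
#'
#' @param fits Named list of [ch_fit()] objects.
#' @param level `"gene"` (default) or `"category"`.
#' @param s_floor Fitness floor before taking logs (default half the
#'   default grid step).
#' @return A list with `nodes`, `edges` (data.frames) and `graph` (an
#'   [igraph::graph] carrying the attributes).
#' @seealso [export_network()]
#' @export
build_network <- function(fits, level = c("gene", "category"),
                          s_floor = 0.0025) {
  level <- match.arg(level)
  vr <- variant_rows(fits, level, s_floor)
  if (!nrow(vr)) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(list(nodes = data.frame(), edges = data.frame(), graph = g))
  }
  labs <- sort(unique(vr$label))
  mean_ls <- vapply(labs, function(l) mean(vr$log_s[vr$label == l]), numeric(1))
  rng <- range(mean_ls)
  color <- if (diff(rng) == 0) rep(0.5, length(labs))
           else (mean_ls - rng[1]) / diff(rng)
  nodes <- data.frame(label = labs,
                      count = as.integer(table(vr$label)[labs]),
                      size = log(as.integer(table(vr$label)[labs])),
                      mean_log_s = mean_ls, color = color,
                      stringsAsFactors = FALSE)
  # count participant-clones containing each unordered label pair
  ecount <- new.env()
  for (pid in names(fits)) {
    fit <- fits[[pid]]
    for (b in seq_along(fit$structure)) {
      block <- fit$structure[[b]]
      if (length(block) < 2L) next
      genes <- vapply(strsplit(block, ":", fixed = TRUE), `[[`, character(1), 1)
      bl <- unique(if (level == "gene") genes else assign_gene_category(genes))
      if (length(bl) < 2L) next
      prs <- utils::combn(sort(bl), 2)
      for (j in seq_len(ncol(prs))) {
        k <- paste(prs[1, j], prs[2, j], sep = "\r")
        ecount[[k]] <- (ecount[[k]] %||% 0L) + 1L
      }
    }
  }
  keys <- ls(ecount)
  edges <- if (length(keys)) {
    sp <- strsplit(keys, "\r", fixed = TRUE)
    data.frame(from = vapply(sp, `[[`, character(1), 1),
               to = vapply(sp, `[[`, character(1), 2),
               count = vapply(keys, function(k) ecount[[k]], integer(1)),
               stringsAsFactors = FALSE)
  } else data.frame(from = character(0), to = character(0), count = integer(0))
  if (nrow(edges))
    edges$mean_log_s <- (nodes$mean_log_s[match(edges$from, nodes$label)] +
                           nodes$mean_log_s[match(edges$to, nodes$label)]) / 2
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges else data.frame(from = character(0), to = character(0)),
    directed = FALSE,
    vertices = data.frame(name = nodes$label, count = nodes$count,
                          size = nodes$size, mean_log_s = nodes$mean_log_s,
                          color = nodes$color))
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges, graph = g)
}

#' Export a network summary
#'
#' Writes the co-occurrence graph as GraphML and/or a JSON adjacency
#' document carrying the node and edge attributes.
#'
#' @param network Result of [build_network()].
#' @param graphml Optional GraphML output path.
#' @param json Optional JSON output path.
#' @return Invisibly, the list of paths written.
#' @export
export_network <- function(network, graphml = NULL, json = NULL) {
  written <- list()
  if (!is.null(graphml)) {
    igraph::write_graph(network$graph, graphml, format = "graphml")
    written$graphml <- graphml
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(nodes = network$nodes, edges = network$edges),
                         json, auto_unbox = TRUE, digits = NA)
    written$json <- json
  }
  invisible(written)
}

#' Brunner-Munzel test
#'
#' Nonparametric two-sample test of the stochastic-equality hypothesis
#' P(X < Y) + 0.5 P(X = Y) = 0.5, robust to unequal variances, with the
#' Brunner-Munzel t approximation.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @return A list with `statistic`, `df`, `p.value` and `p_hat` (the
#'   estimated probability that a value from `y` exceeds one from `x`).
#' @export
brunner_munzel_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2)
    condition_error("each sample needs >= 2 observations", "clonedyn_parameter_error")
  r <- rank(c(x, y))
  r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
  m1 <- mean(r1); m2 <- mean(r2)
  p_hat <- (m2 - (n2 + 1) / 2) / n1
  v1 <- sum((r1 - rank(x) - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - rank(y) - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  vs <- n1 * v1 + n2 * v2
  if (vs == 0) {
    # degenerate: complete separation or all values tied
    if (abs(p_hat - 0.5) < 1e-12)
      return(list(statistic = 0, df = Inf, p.value = 1, p_hat = p_hat))
    return(list(statistic = sign(p_hat - 0.5) * Inf, df = Inf, p.value = 0,
                p_hat = p_hat))
  }
  stat <- n1 * n2 * (m2 - m1) / ((n1 + n2) * sqrt(vs))
  df <- vs^2 / ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  list(statistic = stat, df = df,
       p.value = 2 * stats::pt(-abs(stat), df), p_hat = p_hat)
}

#' Compare fitness of isolated versus co-occurring mutations
#'
#' For each gene (or functional category), tests whether the log fitness of
#' variants occurring alone in a clone differs from that of variants
#' co-occurring with others, using the Brunner-Munzel test with
#' Benjamini-Yekutieli correction across all tests performed. With
#' `grouping = "category"` the per-partner-category contrasts (alone in
#' category A vs co-occurring with category B) are tested as well. Groups
#' with fewer than `min_n` observations in either arm are reported
#' descriptively (`flag = "insufficient"`) and excluded from the
#' correction.
#'
#' @param fits Named list of [ch_fit()] objects.
#' @param grouping `"gene"` or `"category"`.
#' @param min_n Minimum per-arm group size for testing (default 2).
#' @param s_floor Fitness floor before logging (default 0.0025).
#' @return Data.frame with `group`, `partner`, `n_alone`, `n_co`,
#'   `mean_log_s_alone`, `mean_log_s_co`, `statistic`, `p`, `p_adj`,
#'   `flag`.
#' @export
compare_isolated_vs_cooccurring <- function(fits,
                                            grouping = c("gene", "category"),
                                            min_n = 2, s_floor = 0.0025) {
  grouping <- match.arg(grouping)
  vr <- variant_rows(fits, grouping, s_floor)
  vr <- vr[vr$label != "uncategorized", , drop = FALSE]
  res <- list()
  add_contrast <- function(group, partner, alone, co) {
    ok <- length(alone) >= max(min_n, 2) && length(co) >= max(min_n, 2)
    tst <- if (ok) brunner_munzel_test(alone, co) else
      list(statistic = NA_real_, p.value = NA_real_)
    data.frame(group = group, partner = partner,
               n_alone = length(alone), n_co = length(co),
               mean_log_s_alone = if (length(alone)) mean(alone) else NA_real_,
               mean_log_s_co = if (length(co)) mean(co) else NA_real_,
               statistic = tst$statistic, p = tst$p.value,
               flag = if (ok) NA_character_ else "insufficient",
               stringsAsFactors = FALSE)
  }
  for (g in sort(unique(vr$label))) {
    alone <- vr$log_s[vr$label == g & !vr$co]
    co <- vr$log_s[vr$label == g & vr$co]
    res[[length(res) + 1L]] <- add_contrast(g, NA_character_, alone, co)
    if (grouping == "category") {
      partners <- setdiff(unique(unlist(strsplit(vr$partners[vr$label == g & vr$co],
                                                 ","))), "")
      for (p in sort(partners)) {
        with_p <- vr$log_s[vr$label == g & vr$co &
                             grepl(p, vr$partners, fixed = TRUE)]
        res[[length(res) + 1L]] <- add_contrast(g, p, alone, with_p)
      }
    }
  }
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  testable <- is.na(out$flag) & !is.na(out$p)
  out$p_adj[testable] <- stats::p.adjust(out$p[testable], method = "BY")
  rownames(out) <- NULL
  out
}
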