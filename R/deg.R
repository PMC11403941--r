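#' Differential expression from replicate log-ratios
#'
#' Per (gene, treatment): `log2fc` is the mean replicate log2 ratio
#' (treated over control), `p_raw` a two-sided one-sample t-test of the
#' replicate log-ratios against zero (the appropriate test when only
#' treated/control ratios, e.g. from two-colour arrays, are available; the
#' `method` column flags this), and `p_fdr` the Benjamini-Hochberg adjustment
#' across genes within each treatment. Genes with zero replicate variance are
#' degenerate and receive p = 1 with a warning.
#'
#' @param ratios Long-format `data.frame` with columns `gene`, `treatment`,
#'   `log_ratio` (one row per replicate measurement). At least 2 replicates
#'   per (gene, treatment) are required.
#' @return A `data.frame` with one row per (gene, treatment): `gene`,
#'   `treatment`, `log2fc`, `p_raw`, `p_fdr`, `n_rep`, `method`.
#' @export
compute_differential <- function(ratios) {
  stopifnot(all(c("gene", "treatment", "log_ratio") %in% names(ratios)))
  key <- interaction(ratios$gene, ratios$treatment, drop = TRUE, sep = "\r")
  n <- tapply(ratios$log_ratio, key, length)
  if (any(n < 2L)) {
    stop("fewer than 2 replicates for ", sum(n < 2L), " (gene, treatment) pair(s)")
  }
  m <- tapply(ratios$log_ratio, key, mean)
  s <- tapply(ratios$log_ratio, key, stats::sd)
  tstat <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1L)
  degen <- s == 0
  if (any(degen)) {
    warning(sum(degen), " gene/treatment pair(s) with zero replicate ",
            "variance; p set to 1")
    p[degen] <- 1
  }
  parts <- strsplit(names(m), "\r", fixed = TRUE)
  out <- data.frame(
    gene = vapply(parts, `[[`, "", 1L),
    treatment = vapply(parts, `[[`, "", 2L),
    log2fc = as.numeric(m),
    p_raw = as.numeric(p),
    n_rep = as.integer(n),
    method = "t_one_sample",
    stringsAsFactors = FALSE
  )
  out$p_fdr <- stats::ave(out$p_raw, out$treatment,
                          FUN = function(x) stats::p.adjust(x, "BH"))
  out[order(out$treatment, out$gene), c("gene", "treatment", "log2fc",
                                        "p_raw", "p_fdr", "n_rep", "method")]
}

#' Select differentially expressed genes
#'
#' A gene is `up` in a treatment iff `log2fc >= log2(fold)` and
#' `p_fdr < fdr`; `down` symmetrically. Defaults implement the common
#' ">= 2-fold at FDR < 0.05" rule.
#'
#' @param table Expression table from [compute_differential()] (columns
#'   `gene`, `treatment`, `log2fc`, `p_fdr`).
#' @param fold Fold-change threshold (default 2).
#' @param fdr FDR threshold (default 0.05).
#' @return An object of class `deg_partition`: a list with per-treatment
#'   `up`/`down` gene sets plus the thresholds used.
#' @export
select_degs <- function(table, fold = 2, fdr = 0.05) {
  lfc <- log2(fold)
  trts <- sort(unique(table$treatment))
  sets <- lapply(trts, function(tr) {
    rows <- table[table$treatment == tr, , drop = FALSE]
    sig <- rows$p_fdr < fdr
    list(up = sort(rows$gene[sig & rows$log2fc >= lfc]),
         down = sort(rows$gene[sig & rows$log2fc <= -lfc]))
  })
  names(sets) <- trts
  structure(list(treatments = sets, fold = fold, fdr = fdr),
            class = "deg_partition")
}

#' @export
print.deg_partition <- function(x, ...) {
  cat(sprintf("DEG partition (fold >= %g, FDR < %g)\n", x$fold, x$fdr))
  for (tr in names(x$treatments)) {
    cat(sprintf("  %s: %d up, %d down\n", tr,
                length(x$treatments[[tr]]$up),
                length(x$treatments[[tr]]$down)))
  }
  invisible(x)
}

#' Genes regulated in a treatment (up or down)
#'
#' @param partition A `deg_partition`.
#' @param treatment Treatment name; `NULL` returns the union over all.
#' @return Sorted character vector of gene ids.
#' @export
deg_genes <- function(partition, treatment = NULL) {
  sets <- if (is.null(treatment)) partition$treatments else
    partition$treatments[treatment]
  sort(unique(unlist(lapply(sets, function(s) c(s$up, s$down)))))
}

#' Venn region counts for up to four gene sets
#'
#' Every gene of the union is counted in exactly one region; region counts
#' therefore sum to the union size. Region names are the participating set
#' names joined by `&`.
#'
#' @param sets Named list of at most 4 character vectors.
#' @return Named integer vector over the `2^k - 1` regions.
#' @export
venn_partition <- function(sets) {
  k <- length(sets)
  if (k < 1L || k > 4L) stop("venn_partition supports 1 to 4 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("S", seq_len(k))
  }
  univ <- unique(unlist(sets))
  member <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  member <- matrix(member, ncol = k)
  mask <- as.integer(member %*% 2L^(seq_len(k) - 1L))
  regions <- seq_len(2L^k - 1L)
  counts <- vapply(regions, function(r) sum(mask == r), 0L)
  names(counts) <- vapply(regions, function(r) {
    paste(names(sets)[bitwAnd(r, 2L^(seq_len(k) - 1L)) > 0L], collapse = "&")
  }, "")
  counts
}

#' Fold-change magnitude histogram per treatment
#'
#' The absolute fold changes (`2^|log2fc|`) of each treatment's DEGs are
#' binned into left-closed, right-open intervals given by `bin_edges`; per
#' treatment the fractions sum to 1 (an empty treatment gives all-zero
#' fractions with a warning).
#'
#' @param partition A `deg_partition`.
#' @param table The expression table the partition was derived from.
#' @param bin_edges Increasing fold-change edges (default
#'   `c(2, 3, 5, 10, Inf)`).
#' @return Matrix of fractions, treatments in rows, bins in columns.
#' @export
fc_histogram <- function(partition, table, bin_edges = c(2, 3, 5, 10, Inf)) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing")
  }
  nb <- length(bin_edges) - 1L
  bin_names <- paste0("[", bin_edges[-length(bin_edges)], ",",
                      bin_edges[-1L], ")")
  trts <- names(partition$treatments)
  out <- matrix(0, nrow = length(trts), ncol = nb,
                dimnames = list(trts, bin_names))
  for (tr in trts) {
    genes <- deg_genes(partition, tr)
    rows <- table[table$treatment == tr & table$gene %in% genes, ,
                  drop = FALSE]
    if (nrow(rows) == 0L) {
      warning("no DEGs for treatment ", tr, "; all-zero histogram row")
      next
    }
    fold <- 2^abs(rows$log2fc)
    idx <- findInterval(fold, bin_edges, rightmost.closed = FALSE)
    idx <- pmin(pmax(idx, 1L), nb)  # folds below the first edge fall in bin 1
    tab <- tabulate(idx, nbins = nb)
    out[tr, ] <- tab / sum(tab)
  }
  out
}

#' Uncentered correlation
#'
#' `r = sum(x*y) / sqrt(sum(x^2) * sum(y^2))` -- the Pearson-like similarity
#' without mean centering used by the classic expression-clustering tools.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A value in `[-1, 1]`.
#' @export
uncentered_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1L) stop("vectors must be non-empty")
  sx <- sum(x^2); sy <- sum(y^2)
  if (sx == 0 || sy == 0) stop("uncentered correlation undefined for a zero vector")
  r <- sum(x * y) / sqrt(sx * sy)
  min(1, max(-1, r))
}

#' Average-linkage hierarchical clustering on uncentered correlation
#'
#' Distance between genes is `1 - uncentered_correlation` of their
#' fold-change profiles; agglomeration uses standard average linkage
#' (UPGMA via [stats::hclust()]).
#'
#' @param mat Numeric matrix, genes in rows (>= 2), conditions in columns.
#' @return An `hclust` object.
#' @export
hcluster_average <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 rows to cluster")
  norms <- sqrt(rowSums(mat^2))
  zero <- norms == 0
  if (any(zero)) {
    nm <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
    stop("all-zero profile (uncentered correlation undefined) for: ",
         paste(nm[zero], collapse = ", "))
  }
  sim <- tcrossprod(mat / norms)
  sim <- pmin(pmax(sim, -1), 1)  # matrix first: pmin/pmax keep its dim
  d <- stats::as.dist(1 - sim)
  stats::hclust(d, method = "average")
}

#' Delta-delta-Ct fold change
#'
#' With multiple housekeeping normalizers the normalizer Ct is the
#' arithmetic mean of their Cts.
#' `ddCt = (Ct_target,trt - Ct_norm,trt) - (Ct_target,ctl - Ct_norm,ctl)`;
#' fold change `= 2^(-ddCt)`.
#'
#' @param ct_target_trt,ct_target_ctl Target-gene Ct in treated / control.
#' @param ct_norm_trt,ct_norm_ctl Normalizer Ct(s) in treated / control
#'   (vectors allowed).
#' @return Fold change (treated relative to control).
#' @export
ddct_fold_change <- function(ct_target_trt, ct_norm_trt, ct_target_ctl,
                             ct_norm_ctl) {
  ddct <- (ct_target_trt - mean(ct_norm_trt)) -
    (ct_target_ctl - mean(ct_norm_ctl))
  2^(-ddct)
}

#' Hypergeometric over-representation analysis
#'
#' Per annotation term, the upper-tail hypergeometric probability of an
#' overlap at least as large as observed between the query and the term's
#' genes (both intersected with the universe), Benjamini-Hochberg adjusted
#' across terms.
#'
#' @param query Character vector of genes of interest; must be a subset of
#'   `universe`.
#' @param universe Character vector of all assayed genes.
#' @param annotation Named list: term -> character vector of genes.
#' @param fdr Adjusted-p threshold used for the `enriched` flag
#'   (default 0.05).
#' @return `data.frame` with columns `term`, `n_term`, `n_overlap`, `p`,
#'   `p_adj`, `enriched`, sorted by `p`.
#' @export
ora <- function(query, universe, annotation, fdr = 0.05) {
  query <- unique(query); universe <- unique(universe)
  stray <- setdiff(query, universe)
  if (length(stray)) {
    stop("query gene(s) not in universe: ", paste(stray, collapse = ", "))
  }
  N <- length(universe); q <- length(query)
  res <- lapply(names(annotation), function(term) {
    tg <- intersect(unique(annotation[[term]]), universe)
    ov <- length(intersect(tg, query))
    p <- stats::phyper(ov - 1L, length(tg), N - length(tg), q,
                       lower.tail = FALSE)
    data.frame(term = term, n_term = length(tg), n_overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, "BH")
  out$enriched <- out$p_adj < fdr
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-reference DEGs against an external target-gene list
#'
#' @param deg Character vector of differentially expressed genes.
#' @param targets `data.frame` with columns `gene` and `evidence` (per-gene
#'   evidence count, e.g. number of independent datasets confirming binding).
#' @return `data.frame` with one row per DEG: `gene`, `in_targets`,
#'   `evidence` (0 when absent), sorted by evidence descending then gene.
#' @export
crossref_targets <- function(deg, targets) {
  deg <- unique(deg)
  idx <- match(deg, targets$gene)
  out <- data.frame(
    gene = deg,
    in_targets = !is.na(idx),
    evidence = ifelse(is.na(idx), 0L, targets$evidence[idx]),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$evidence, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
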