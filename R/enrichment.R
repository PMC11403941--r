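#' Per-set binding-site coverage and density
#'
#' Scans every promoter of a set on both strands and aggregates: total hit
#' count, total bp scanned, sites per 1000 bp, and the fraction of promoters
#' carrying at least one hit.
#'
#' @param promoters Promoter table (`gene_id`/`id` and `seq` columns);
#'   must be non-empty.
#' @param pwm A `pwm` object.
#' @param mss_cutoff,css_cutoff Score cutoffs (see [scan_pwm()]).
#' @return An object of class `density_stats`: list with `n_sites`,
#'   `total_bp`, `per_kb`, `n_promoters`, `n_promoters_with_site`,
#'   `coverage_fraction`, plus `hits` (the pooled hit table) and
#'   `per_promoter` (per-promoter id, length and hit count, used by the
#'   permutation test).
#' @export
promoter_coverage <- function(promoters, pwm, mss_cutoff = 0.75,
                              css_cutoff = 0.80) {
  if (is.null(promoters) || nrow(promoters) == 0L) {
    stop("empty promoter set")
  }
  ids <- promoters$id %||% promoters$gene_id
  hits <- scan_promoters(pwm, promoters, mss_cutoff, css_cutoff,
                         both_strands = TRUE)
  n_hit <- vapply(ids, function(g) sum(hits$promoter_id == g), 0L)
  total_bp <- sum(nchar(promoters$seq))
  structure(list(
    n_sites = nrow(hits),
    total_bp = total_bp,
    per_kb = site_density(hits, total_bp),
    n_promoters = nrow(promoters),
    n_promoters_with_site = sum(n_hit > 0L),
    coverage_fraction = mean(n_hit > 0L),
    hits = hits,
    per_promoter = data.frame(id = ids, length = nchar(promoters$seq),
                              n_sites = unname(n_hit),
                              stringsAsFactors = FALSE)
  ), class = "density_stats")
}

#' @export
print.density_stats <- function(x, ...) {
  cat(sprintf(paste0("%d sites over %d bp (%.3f per 1000 bp); %d/%d ",
                     "promoters with >= 1 site (coverage %.1f%%)\n"),
              x$n_sites, x$total_bp, x$per_kb, x$n_promoters_with_site,
              x$n_promoters, 100 * x$coverage_fraction))
  invisible(x)
}

#' Site-density enrichment of a foreground over a background promoter set
#'
#' Three tests are available. `binomial_conditional` conditions on the total
#' site count `n = fg + bg` and tests the foreground count against success
#' probability `p0 = fg_bp / (fg_bp + bg_bp)` (exact binomial).
#' `poisson_rate` is the exact two-sample Poisson rate comparison on the
#' counts with the scanned bp as exposures. `permutation` shuffles promoter
#' labels between the two sets and recomputes the per-kb density difference,
#' with `p = (1 + #{perm >= obs}) / (1 + reps)`.
#'
#' @param fg,bg `density_stats` objects from [promoter_coverage()].
#' @param method One of `"binomial_conditional"`, `"poisson_rate"`,
#'   `"permutation"`.
#' @param alternative `"greater"` (foreground enriched) or `"two_sided"`.
#' @param n_perm Number of permutations (default 10000).
#' @return An object of class `enrichment_result`: list with `fg`, `bg`,
#'   `method`, `alternative`, `statistic` (foreground minus background
#'   density per kb) and `p_value`.
#' @export
density_enrichment <- function(fg, bg,
                               method = c("binomial_conditional",
                                          "poisson_rate", "permutation"),
                               alternative = c("greater", "two_sided"),
                               n_perm = 10000L) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  stopifnot(inherits(fg, "density_stats"), inherits(bg, "density_stats"))
  alt <- if (alternative == "greater") "greater" else "two.sided"
  stat <- fg$per_kb - bg$per_kb
  p <- switch(method,
    binomial_conditional = {
      n <- fg$n_sites + bg$n_sites
      if (n == 0L) {
        warning("zero total sites; binomial test uninformative, p = 1")
        1
      } else {
        p0 <- fg$total_bp / (fg$total_bp + bg$total_bp)
        stats::binom.test(fg$n_sites, n, p0, alternative = alt)$p.value
      }
    },
    poisson_rate = stats::poisson.test(
      c(fg$n_sites, bg$n_sites), c(fg$total_bp, bg$total_bp),
      alternative = alt)$p.value,
    permutation = {
      pp <- rbind(fg$per_promoter, bg$per_promoter)
      n_fg <- nrow(fg$per_promoter)
      obs <- stat
      perm <- vapply(seq_len(n_perm), function(i) {
        sel <- sample.int(nrow(pp), n_fg)
        d_fg <- 1000 * sum(pp$n_sites[sel]) / sum(pp$length[sel])
        d_bg <- 1000 * sum(pp$n_sites[-sel]) / sum(pp$length[-sel])
        d_fg - d_bg
      }, 0)
      if (alternative == "greater") {
        (1 + sum(perm >= obs)) / (1 + n_perm)
      } else {
        (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm)
      }
    })
  structure(list(fg = fg, bg = bg, method = method,
                 alternative = alternative, statistic = stat, p_value = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s enrichment: %.3f vs %.3f sites/kb (diff %.3f), p = %.4g\n",
              x$method, x$fg$per_kb, x$bg$per_kb, x$statistic, x$p_value))
  invisible(x)
}

#' Flanking windows around anchor binding-site hits
#'
#' One window per anchor hit: `[site_start - flank, site_end + flank)` in
#' promoter coordinates, clipped at the promoter ends (clipping is reported
#' with a message). With the default 100 bp flank and a typical 12 bp
#' matrix this yields windows of roughly 200 bp plus the site.
#'
#' @param hits Hit table from [scan_promoters()] (anchor matrix).
#' @param promoters Promoter table the hits refer to.
#' @param pwm_length Length of the anchor matrix (bp of the site itself).
#' @param flank Flank size in bp on each side (default 100).
#' @return `data.frame` with columns `promoter_id`, `start`, `end`,
#'   `anchor_offset`, `anchor_strand`, `seq`.
#' @export
anchor_windows <- function(hits, promoters, pwm_length, flank = 100L) {
  ids <- promoters$id %||% promoters$gene_id
  unknown <- setdiff(unique(hits$promoter_id), ids)
  if (length(unknown)) {
    stop("hit(s) reference unknown promoter(s): ",
         paste(unknown, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(hits)), function(i) {
    pid <- hits$promoter_id[i]
    pseq <- promoters$seq[match(pid, ids)]
    plen <- nchar(pseq)
    s <- hits$offset[i] - flank
    e <- hits$offset[i] + pwm_length + flank
    if (s < 0L || e > plen) {
      message("clipping anchor window at promoter '", pid, "' ends")
      s <- max(s, 0L); e <- min(e, plen)
    }
    data.frame(promoter_id = pid, start = s, end = e,
               anchor_offset = hits$offset[i],
               anchor_strand = hits$strand[i],
               seq = substring(pseq, s + 1L, e), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(promoter_id = character(), start = integer(),
                      end = integer(), anchor_offset = integer(),
                      anchor_strand = character(), seq = character(),
                      stringsAsFactors = FALSE)
  }
  res
}

#' Composite-module discovery around anchor sites
#'
#' For each secondary matrix of the library, windows are classified by the
#' presence of at least one hit; the 2x2 contingency of presence in the
#' positive (anchor-containing, regulated) windows versus the contrast
#' windows is tested with a one-sided Fisher exact test (enrichment in the
#' positives), Benjamini-Hochberg adjusted across the library, and ranked by
#' ascending p. A library entry sharing the anchor's matrix name is skipped
#' with a warning. The positive-vs-"false-positive" and
#' positive-vs-"negative" profile designs differ only in the contrast set
#' supplied.
#'
#' @param positive `data.frame` of anchor windows (column `seq`), >= 2 rows.
#' @param contrast `data.frame` of contrast windows or sequences (column
#'   `seq`), >= 2 rows.
#' @param library List of `pwm` objects (the secondary matrix candidates).
#' @param anchor_name Name of the anchor matrix, excluded from the library.
#' @param mss_cutoff,css_cutoff Score cutoffs for secondary-site presence.
#' @return `data.frame` with one row per secondary matrix: `anchor`,
#'   `secondary`, contingency counts `a`, `b`, `c`, `d` (positive with /
#'   without, contrast with / without a site), `p`, `p_adj`, `rank`.
#' @export
module_discovery <- function(positive, contrast, library, anchor_name = NULL,
                             mss_cutoff = 0.75, css_cutoff = 0.80) {
  if (nrow(positive) < 2L || nrow(contrast) < 2L) {
    stop("need at least 2 positive and 2 contrast windows")
  }
  if (length(library) == 0L) stop("empty matrix library")
  nm <- vapply(library, function(p) p$name, "")
  if (!is.null(anchor_name) && any(nm == anchor_name)) {
    warning("anchor matrix '", anchor_name, "' present in library; skipped")
    library <- library[nm != anchor_name]
    nm <- nm[nm != anchor_name]
    if (length(library) == 0L) stop("library contains only the anchor matrix")
  }
  has_site <- function(seqs, pwm) {
    vapply(seqs, function(s) {
      nrow(scan_pwm(pwm, list(id = "w", seq = s), mss_cutoff, css_cutoff,
                    both_strands = TRUE)) > 0L
    }, logical(1L), USE.NAMES = FALSE)
  }
  rows <- lapply(seq_along(library), function(i) {
    pos <- has_site(positive$seq, library[[i]])
    con <- has_site(contrast$seq, library[[i]])
    a <- sum(pos); b <- sum(!pos); c_ <- sum(con); d <- sum(!con)
    p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE),
                            alternative = "greater")$p.value
    data.frame(anchor = anchor_name %||% NA_character_, secondary = nm[i],
               a = a, b = b, c = c_, d = d, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, "BH")
  out <- out[order(out$p, out$secondary), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
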