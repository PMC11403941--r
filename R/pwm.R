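#' Build a position weight matrix from aligned binding sites
#'
#' Counts are tallied per position over the fixed column order A,C,G,T.
#' Frequencies use an additive pseudocount `p` shared across bases:
#' `f(i,b) = (c(i,b) + p/4) / (n_sites + p)`. The per-position information
#' weight is `I(i) = sum_b f(i,b) * log(4 * f(i,b))` (natural log, with
#' `0*log(0) := 0`), bounded by `[0, log(4)]`. The core is the contiguous run
#' of `core_length` positions maximising the summed information weight
#' (leftmost on ties).
#'
#' @param sites Character vector of at least two equal-length, unambiguous
#'   (\{A,C,G,T\}) aligned binding-site sequences.
#' @param pseudocount Non-negative pseudocount `p` (default 1).
#' @param name Matrix name.
#' @param core_length Number of consecutive core positions (default 5,
#'   truncated to the matrix length).
#' @return An object of class `pwm`: list with `name`, `counts`, `n_sites`,
#'   `pseudocount`, `freq` (L x 4), `info` (length L), `core_positions`.
#' @examples
#' p <- build_pwm(c("ACGT", "ACGT", "ACGT"), pseudocount = 0)
#' consensus(p)
#' @export
build_pwm <- function(sites, pseudocount = 1, name = "pwm", core_length = 5L) {
  if (length(sites) < 2L) stop("need at least 2 sites")
  sites <- toupper(sites)
  L <- unique(nchar(sites))
  if (length(L) != 1L) stop("sites must have identical length")
  if (any(grepl("[^ACGT]", sites))) {
    stop("sites must be unambiguous over {A,C,G,T}")
  }
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  mat <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  counts <- vapply(DNA_BASES, function(b) colSums(mat == b),
                   numeric(L))
  counts <- matrix(counts, nrow = L, ncol = 4L,
                   dimnames = list(NULL, DNA_BASES))
  pwm_from_counts(counts, n_sites = length(sites), pseudocount = pseudocount,
                  name = name, core_length = core_length)
}

#' Turn a count matrix into a scoring PWM
#'
#' @param x A `pwm_counts` object (e.g. from [read_matrix_transfac()]).
#' @inheritParams build_pwm
#' @return A `pwm` object (see [build_pwm()]).
#' @export
as_pwm <- function(x, pseudocount = 1, core_length = 5L) {
  stopifnot(inherits(x, "pwm_counts") || inherits(x, "pwm"))
  if (inherits(x, "pwm")) return(x)
  n_sites <- max(rowSums(x$counts))
  pwm_from_counts(x$counts, n_sites = n_sites, pseudocount = pseudocount,
                  name = x$name, core_length = core_length)
}

pwm_from_counts <- function(counts, n_sites, pseudocount, name,
                            core_length = 5L) {
  L <- nrow(counts)
  freq <- (counts + pseudocount / 4) / (rowSums(counts) + pseudocount)
  info <- apply(freq, 1L, function(f) {
    terms <- ifelse(f > 0, f * log(4 * f), 0)
    sum(terms)
  })
  k <- min(as.integer(core_length), L)
  wins <- L - k + 1L
  win_sums <- vapply(seq_len(wins), function(s) sum(info[s:(s + k - 1L)]),
                     0)
  s <- which.max(win_sums)  # leftmost maximum
  structure(list(
    name = name,
    counts = counts,
    n_sites = n_sites,
    pseudocount = pseudocount,
    freq = freq,
    info = info,
    core_positions = s:(s + k - 1L)
  ), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': %d positions, %d sites, pseudocount %g\n",
              x$name, nrow(x$counts), x$n_sites, x$pseudocount))
  cat("consensus:", consensus(x, 1L), "  core positions:",
      paste(range(x$core_positions), collapse = "-"), "\n")
  invisible(x)
}

#' Rank-k consensus sequence of a PWM
#'
#' Position-wise the rank-th most frequent base, with ties broken by fixed
#' alphabet order A < C < G < T. Rank 1 gives the consensus, rank 2 the
#' degenerate ("second-best") consensus.
#'
#' @param pwm A `pwm` object.
#' @param rank Integer in 1..4.
#' @return A single sequence string.
#' @export
consensus <- function(pwm, rank = 1L) {
  rank <- as.integer(rank)
  if (rank < 1L || rank > 4L) stop("rank must be in 1..4")
  bases <- apply(pwm$freq, 1L, function(f) {
    DNA_BASES[order(-f, seq_along(f))][rank]
  })
  paste(bases, collapse = "")
}

#' MATCH-style matrix and core similarity scores for one window
#'
#' The match score of window `b_1..b_L` is
#' `Current = sum_i I(i) * f(i, b_i)`, min-max normalised per matrix:
#' `mss = (Current - Min) / (Max - Min)` with `Min`/`Max` the
#' information-weighted per-position minimum/maximum frequencies. The core
#' similarity `css` is the same quantity restricted to the core positions.
#' An `N` base contributes the column-minimum frequency (conservative). When
#' a matrix carries no information (`Max == Min`), the score is defined as 1
#' for every window.
#'
#' @param pwm A `pwm` object.
#' @param window A string of length equal to the matrix length, over
#'   \{A,C,G,T,N\}.
#' @return Named numeric vector `c(mss =, css =)`, both in `[0, 1]`.
#' @export
match_score <- function(pwm, window) {
  L <- nrow(pwm$freq)
  window <- toupper(window)
  if (nchar(window) != L) {
    stop("window length ", nchar(window), " does not match matrix length ", L)
  }
  codes <- encode_seq(window)
  fmat <- cbind(pwm$freq, N = apply(pwm$freq, 1L, min))
  fb <- fmat[cbind(seq_len(L), codes)]
  score_span <- function(idx) {
    I <- pwm$info[idx]
    cur <- sum(I * fb[idx])
    lo <- sum(I * apply(pwm$freq[idx, , drop = FALSE], 1L, min))
    hi <- sum(I * apply(pwm$freq[idx, , drop = FALSE], 1L, max))
    if (hi - lo <= 0) return(1)
    (cur - lo) / (hi - lo)
  }
  c(mss = score_span(seq_len(L)), css = score_span(pwm$core_positions))
}

# Precompute scanning tables for a pwm: weighted frequency matrix with the N
# column, and min/max normalisation constants for full matrix and core.
scan_tables <- function(pwm) {
  L <- nrow(pwm$freq)
  fmat <- cbind(pwm$freq, N = apply(pwm$freq, 1L, min))
  W <- fmat * pwm$info  # L x 5, row i weighted by I(i)
  lo_i <- pwm$info * apply(pwm$freq, 1L, min)
  hi_i <- pwm$info * apply(pwm$freq, 1L, max)
  core <- pwm$core_positions
  list(W = W, L = L,
       lo = sum(lo_i), hi = sum(hi_i),
       lo_core = sum(lo_i[core]), hi_core = sum(hi_i[core]),
       core = core)
}

# Vectorised window scores along an encoded sequence; returns data.frame of
# offsets (0-based) with mss/css for all windows.
score_all_windows <- function(tab, codes) {
  n <- length(codes)
  L <- tab$L
  n_win <- n - L + 1L
  if (n_win < 1L) return(NULL)
  cur <- numeric(n_win)
  cur_core <- numeric(n_win)
  for (i in seq_len(L)) {
    w <- tab$W[i, codes[i:(i + n_win - 1L)]]
    cur <- cur + w
    if (i %in% tab$core) cur_core <- cur_core + w
  }
  mss <- if (tab$hi - tab$lo > 0) (cur - tab$lo) / (tab$hi - tab$lo) else
    rep(1, n_win)
  css <- if (tab$hi_core - tab$lo_core > 0)
    (cur_core - tab$lo_core) / (tab$hi_core - tab$lo_core) else rep(1, n_win)
  data.frame(offset = 0:(n_win - 1L), mss = mss, css = css)
}

empty_hits <- function() {
  data.frame(promoter_id = character(), offset = integer(),
             strand = character(), mss = numeric(), css = numeric(),
             site_seq = character(), stringsAsFactors = FALSE)
}

#' Scan a promoter sequence with a PWM
#'
#' Every window on the forward strand and (optionally) on the reverse
#' complement whose core similarity and matrix similarity meet the cutoffs is
#' reported exactly once. Offsets are 0-based starts in forward-strand
#' coordinates; `site_seq` is the matched L-mer in matrix orientation.
#' Overlapping hits are all reported. The default cutoffs are deliberately
#' low so that false negatives are minimised; raise them for specific scans.
#'
#' @param pwm A `pwm` object.
#' @param promoter Either a single sequence string or a one-row
#'   `data.frame`/list with fields `id` and `seq`.
#' @param mss_cutoff,css_cutoff Score cutoffs in `[0, 1]`
#'   (defaults 0.75 / 0.80).
#' @param both_strands Scan the reverse complement as well (default `TRUE`).
#' @return A `data.frame` with columns `promoter_id`, `offset`, `strand`,
#'   `mss`, `css`, `site_seq`, sorted by offset then strand (`+` before `-`).
#'   A promoter shorter than the matrix yields zero rows (with a message).
#' @export
scan_pwm <- function(pwm, promoter, mss_cutoff = 0.75, css_cutoff = 0.80,
                     both_strands = TRUE) {
  if (mss_cutoff < 0 || mss_cutoff > 1 || css_cutoff < 0 || css_cutoff > 1) {
    stop("cutoffs must be in [0, 1]")
  }
  if (is.character(promoter) && length(promoter) == 1L) {
    promoter <- list(id = "promoter", seq = promoter)
  }
  seq <- toupper(promoter$seq)
  id <- promoter$id
  L <- nrow(pwm$freq)
  n <- nchar(seq)
  if (n < L) {
    message("promoter '", id, "' shorter than matrix (", n, " < ", L,
            "); no windows scanned")
    return(empty_hits())
  }
  tab <- scan_tables(pwm)
  keep_hits <- function(sc, strand, seq_used) {
    sel <- sc$mss >= mss_cutoff & sc$css >= css_cutoff
    if (!any(sel)) return(NULL)
    sc <- sc[sel, , drop = FALSE]
    site <- substring(seq_used, sc$offset + 1L, sc$offset + L)
    fwd_off <- if (strand == "+") sc$offset else n - L - sc$offset
    data.frame(promoter_id = id, offset = fwd_off, strand = strand,
               mss = sc$mss, css = sc$css, site_seq = site,
               stringsAsFactors = FALSE)
  }
  codes <- encode_seq(seq)
  out <- list(keep_hits(score_all_windows(tab, codes), "+", seq))
  if (both_strands) {
    rc <- revcomp(seq)
    out <- c(out, list(keep_hits(score_all_windows(tab, encode_seq(rc)),
                                 "-", rc)))
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_hits())
  out <- out[order(out$offset, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of promoters with a PWM
#'
#' @param pwm A `pwm` object.
#' @param promoters A `data.frame` with columns `id` and `seq`.
#' @inheritParams scan_pwm
#' @return Row-bound hit table over all promoters (see [scan_pwm()]).
#' @export
scan_promoters <- function(pwm, promoters, mss_cutoff = 0.75,
                           css_cutoff = 0.80, both_strands = TRUE) {
  ids <- promoters$id %||% promoters$gene_id
  out <- lapply(seq_len(nrow(promoters)), function(i) {
    scan_pwm(pwm, list(id = ids[i], seq = promoters$seq[i]),
             mss_cutoff, css_cutoff, both_strands)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) empty_hits() else res
}

#' Binding-site density per 1000 bp
#'
#' @param hits A hit table (any object with rows per hit) or an integer
#'   number of hits.
#' @param total_bp Total sequence length scanned, in bp (> 0).
#' @return Sites per 1000 bp.
#' @export
site_density <- function(hits, total_bp) {
  if (total_bp <= 0) stop("total_bp must be positive")
  n <- if (is.data.frame(hits)) nrow(hits) else as.numeric(hits)
  1000 * n / total_bp
}
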