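# Independent oracles, written directly from the definitions and kept free of
# the package's scanning/clustering code paths.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rand_sites <- function(n_sites, L) {
  vapply(seq_len(n_sites), function(i) rand_seq(L), "")
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Recompute frequencies, information weights, core and the min-max normalised
# match score from the raw counts by direct arithmetic.
oracle_match <- function(counts, pseudocount, window, core_length = 5L) {
  L <- nrow(counts)
  freq <- (counts + pseudocount / 4) / (rowSums(counts) + pseudocount)
  info <- numeric(L)
  for (i in seq_len(L)) {
    for (b in 1:4) {
      if (freq[i, b] > 0) info[i] <- info[i] + freq[i, b] * log(4 * freq[i, b])
    }
  }
  k <- min(core_length, L)
  best <- -Inf; best_s <- 1L
  for (s in 1:(L - k + 1L)) {
    v <- sum(info[s:(s + k - 1L)])
    if (v > best + 1e-12) { best <- v; best_s <- s }
  }
  core <- best_s:(best_s + k - 1L)
  chars <- strsplit(window, "")[[1]]
  span_score <- function(idx) {
    cur <- lo <- hi <- 0
    for (i in idx) {
      fb <- if (chars[i] == "N") min(freq[i, ]) else
        freq[i, match(chars[i], BASES)]
      cur <- cur + info[i] * fb
      lo <- lo + info[i] * min(freq[i, ])
      hi <- hi + info[i] * max(freq[i, ])
    }
    if (hi - lo <= 0) 1 else (cur - lo) / (hi - lo)
  }
  c(mss = unname(span_score(1:L)), css = unname(span_score(core)))
}

# Exhaustive both-strand scan using oracle_match only.
oracle_scan <- function(counts, pseudocount, seq, mss_cutoff, css_cutoff,
                        core_length = 5L) {
  L <- nrow(counts)
  n <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s_used <- if (strand == "+") seq else oracle_revcomp(seq)
    for (off in 0:(n - L)) {
      win <- substring(s_used, off + 1, off + L)
      sc <- oracle_match(counts, pseudocount, win, core_length)
      if (sc["mss"] >= mss_cutoff && sc["css"] >= css_cutoff) {
        fwd <- if (strand == "+") off else n - L - off
        rows[[length(rows) + 1]] <- data.frame(
          offset = fwd, strand = strand, mss = unname(sc["mss"]),
          css = unname(sc["css"]), site_seq = win, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(offset = integer(), strand = character(),
                      mss = numeric(), css = numeric(),
                      site_seq = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$offset, match(out$strand, c("+", "-"))), ]
  rownames(out) <- NULL
  out
}

# Naive O(n^3) average-linkage agglomeration on a distance matrix: recompute
# all active pairwise cluster distances at every step.
oracle_average_linkage_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- 0
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best - 1e-12) { best <- dd; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# PWM with a sharp information profile, used where chance background matches
# must be negligible.
sharp_pwm <- function(L = 10L, pseudocount = 1, name = "sharp") {
  cons <- sample(BASES, L, replace = TRUE)
  counts <- matrix(0L, nrow = L, ncol = 4, dimnames = list(NULL, BASES))
  for (i in seq_len(L)) counts[i, cons[i]] <- 40L
  counts[cbind(seq_len(L), (match(cons, BASES) %% 4) + 1L)] <- 4L
  as_pwm(pwm_counts(counts, name), pseudocount = pseudocount)
}

rand_pwm <- function(L, n_sites = 12L, pseudocount = 1) {
  build_pwm(rand_sites(n_sites, L), pseudocount = pseudocount,
            name = sprintf("rand%d", L))
}
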