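# Shared fixtures and independent oracles for the test suite.

# Small-frame scenario spec for fast tests; geometry is scaled down but the
# default window length (k = 30) still fits every sequence.
small_spec <- function(scenario, seed, ...) {
  scenario_spec(scenario, frame_size = c(90L, 120L),
                person_size = c(36L, 12L), seed = seed, ...)
}

# Build a frame (background + planted intensity blob) from a mask.
planted_frame <- function(mask, bg_level = 120, person_level = 220) {
  fr <- matrix(bg_level, nrow(mask), ncol(mask))
  fr[mask] <- person_level
  fr
}

# Brute-force per-pixel median oracle.
oracle_median_stack <- function(frames) {
  out <- frames[[1]]
  for (r in seq_len(nrow(out))) for (cc in seq_len(ncol(out))) {
    v <- sort(vapply(frames, function(f) f[r, cc], numeric(1)))
    n <- length(v)
    out[r, cc] <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }
  out
}

# Brute-force boundary set: component pixels with a 4-neighbour outside.
oracle_boundary <- function(mask) {
  pts <- NULL
  nr <- nrow(mask); nc <- ncol(mask)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!mask[r, cc]) next
    nb <- c(if (r > 1) mask[r - 1, cc] else FALSE,
            if (r < nr) mask[r + 1, cc] else FALSE,
            if (cc > 1) mask[r, cc - 1] else FALSE,
            if (cc < nc) mask[r, cc + 1] else FALSE)
    if (!all(nb)) pts <- rbind(pts, c(x = cc, y = r))
  }
  pts
}

# Two-pass textbook variance with denominator k.
oracle_variance <- function(series, k) {
  w <- series[(length(series) - k + 1):length(series)]
  mu <- sum(w) / k
  sum((w - mu)^2) / k
}

# Exhaustive gain-ratio split search (independent of best_split internals).
oracle_best_split <- function(X, y, w = NULL) {
  n <- nrow(X)
  w <- if (is.null(w)) rep(1 / n, n) else w / sum(w)
  classes <- sort(unique(y))
  ent <- function(wts) {
    p <- wts / sum(wts); p <- p[p > 0]
    -sum(p * log2(p))
  }
  tot <- sapply(classes, function(cl) sum(w[y == cl]))
  h0 <- ent(tot)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2) next
    for (m in seq_len(length(vals) - 1)) {
      thr <- (vals[m] + vals[m + 1]) / 2
      left <- X[, j] <= thr
      wl <- sum(w[left]); wr <- 1 - wl
      hl <- ent(sapply(classes, function(cl) sum(w[left & y == cl])))
      hr <- ent(sapply(classes, function(cl) sum(w[!left & y == cl])))
      gain <- h0 - (wl * hl + wr * hr)
      si <- ent(c(wl, wr))
      if (gain > 1e-12 && si > 0) {
        gr <- gain / si
        # same tolerance-aware tie-break as the implementation contract:
        # lowest attribute, then lowest threshold, among near-equal ratios
        if (is.null(best) || gr > best$gain_ratio + 1e-9)
          best <- list(attribute = j, threshold = thr, gain_ratio = gr)
      }
    }
  }
  best
}

# All-pairs concordance statistic: P(margin+ > margin-) + 0.5 P(tie).
oracle_concordance <- function(margins, y, positive) {
  mp <- margins[y == positive]; mn <- margins[y != positive]
  tot <- 0
  for (a in mp) for (b in mn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(mp) * length(mn))
}

# Labelled window features for a set of simulated sequences (cached, since
# several test files reuse the same synthetic datasets).
.feature_cache <- new.env(parent = emptyenv())
cached_features <- function(scenario, seeds, spec_fun = small_spec) {
  key <- paste(scenario, paste(seeds, collapse = ","),
               deparse(substitute(spec_fun)), sep = "|")
  if (is.null(.feature_cache[[key]])) {
    .feature_cache[[key]] <- do.call(rbind, lapply(seeds, function(s) {
      sim <- simulate_sequence(spec_fun(scenario, seed = s), keep_masks = FALSE)
      extract_features(sim$sequence, sim$truth)
    }))
  }
  .feature_cache[[key]]
}

feature_matrix <- function(df) {
  as.matrix(df[grep("^var_", names(df), value = TRUE)])
}

# Confusion object with prescribed TP/FN/TN/FP counts.
fake_counts <- function(tp, fn, tn, fp) {
  y <- c(rep("fall", tp + fn), rep("no_fall", tn + fp))
  p <- c(rep("fall", tp), rep("no_fall", fn), rep("no_fall", tn),
         rep("fall", fp))
  confusion(y, p)
}
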