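# internal helpers shared across modules

# Deterministic child seed from a parent seed plus arbitrary tags.
# Polynomial string hash kept inside the 32-bit signed range so the result is
# always a valid set.seed() argument.
derive_seed <- function(seed, ...) {
  parts <- c(as.character(seed), vapply(list(...), as.character, character(1)))
  h <- 0
  for (p in parts) {
    for (ch in utf8ToInt(p)) h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# stream.
local_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Union of half-open intervals. `m` is a 2-column matrix (start, end); rows
# with end <= start are dropped. Intervals closer than `gap` (or abutting,
# with gap = 0) are merged.
merge_intervals <- function(m, gap = 0) {
  m <- matrix(as.numeric(m), ncol = 2)
  m <- m[m[, 2] > m[, 1], , drop = FALSE]
  if (nrow(m) == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      k <- nrow(out)
      if (m[i, 1] <= out[k, 2] + gap) {
        out[k, 2] <- max(out[k, 2], m[i, 2])
      } else {
        out <- rbind(out, m[i, , drop = FALSE])
      }
    }
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

# Overlap length between one interval [a1, a2) and each row of `m`.
interval_overlap <- function(a1, a2, m) {
  if (nrow(m) == 0) return(numeric(0))
  pmax(0, pmin(a2, m[, 2]) - pmax(a1, m[, 1]))
}

# Moving average with shrinking windows at the edges (no phase shift, no NA).
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  n <- length(x)
  half <- width %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Smallest 5-smooth integer >= n (fast FFT length for R's mixed-radix fft).
next_fast_len <- function(n) {
  if (n <= 2) return(max(1L, n))
  best <- 2^ceiling(log2(n))
  p5 <- 1
  while (p5 < best) {
    p35 <- p5
    while (p35 < best) {
      m <- p35 * 2^ceiling(log2(n / p35))
      if (m >= n && m < best) best <- m
      p35 <- p35 * 3
    }
    p5 <- p5 * 5
  }
  as.integer(best)
}

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), NA_character_, formatC(signif(x, digits), format = "g", digits = digits))
}
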