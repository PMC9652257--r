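# Independent oracles used across test files.

# Spearman rho via the definition: Pearson correlation of average ranks,
# computed with explicit tie handling (mean of occupied positions).
spearman_bruteforce <- function(a, b) {
  avg_rank <- function(v) {
    pos <- order(v)
    r <- numeric(length(v))
    r[pos] <- seq_along(v)
    tapply_ranks <- tapply(r, v, mean)
    unname(tapply_ranks[as.character(v)])
  }
  ra <- avg_rank(a)
  rb <- avg_rank(b)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}

# Closed-form 2x2 odds ratio with Wald interval:
# a/b = events/non-events in the exposed class, c/d in the reference.
or_2x2 <- function(a, b, c, d) {
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- log(or) / se
  list(or = or, ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se),
       p = 2 * stats::pnorm(-abs(z)))
}

# Enumerate a representative grid of resection targets covering the full
# discrete feature domain of the scoring rules: every type, every singleton
# and pair of segments plus canonical multi-segment sets, both tumor-size
# sides of each threshold, and every flag combination handled by the caller.
target_grid <- function() {
  vocab <- segment_vocabulary()
  singles <- as.list(vocab)
  pairs <- utils::combn(vocab, 2, simplify = FALSE)
  multis <- list(c("2", "3"), c("5", "6", "7"), c("6", "7", "8"),
                 c("2", "3", "4a", "4b"), c("5", "6", "7", "8"),
                 c("4a", "4b", "5", "8"), c("4a", "4b", "5", "6", "7", "8"))
  segsets <- c(singles, pairs, multis)
  grid <- expand.grid(type = resection_types_all(),
                      seg = seq_along(segsets),
                      stringsAsFactors = FALSE)
  grid$segments <- segsets[grid$seg]
  grid
}

resection_types_all <- function() {
  c("wedge", "anatomical_segmentectomy", "left_lateral_sectionectomy",
    "sectionectomy_other", "left_hepatectomy", "right_hepatectomy",
    "central_hepatectomy", "extended_hepatectomy")
}
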