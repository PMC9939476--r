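# internal helpers: classed conditions, deterministic rounding/allocation

fnafs_abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "fnafs_error"), call = call))
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) >= 1L && !anyNA(x) && all(x >= 0) &&
    all(abs(x - round(x)) < 1e-8)
}

# round half-up (not banker's): percent display convention, one decimal
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

pct1 <- function(x) round_half_up(100 * x, 1L)

# Largest-remainder apportionment of an integer `total` proportional to
# `weights`, each share clamped to [floors[i], caps[i]]. Deterministic:
# remainder ties broken by position. Errors if the box constraints make
# `total` unreachable.
allocate_lr <- function(total, weights, caps = rep(Inf, length(weights)),
                        floors = rep(0, length(weights))) {
  k <- length(weights)
  stopifnot(length(caps) == k, length(floors) == k)
  floors <- pmax(floors, 0)
  if (sum(floors) - 1e-9 > total || sum(caps) + 1e-9 < total) {
    fnafs_abort(
      sprintf("cannot apportion %d units within [%s, %s]",
              total, sum(floors), sum(caps)),
      "fnafs_infeasible_error")
  }
  if (total == 0) return(floors)
  w <- if (sum(weights) > 0) weights / sum(weights) else rep(1 / k, k)
  target <- total * w
  x <- pmin(pmax(floor(target), floors), caps)
  rem <- target - floor(target)
  # distribute the shortfall one unit at a time, largest remainder first,
  # skipping capped cells; ties resolved by index order
  ord <- order(-rem, seq_len(k))
  while (sum(x) < total) {
    placed <- FALSE
    for (i in ord) {
      if (x[i] < caps[i]) {
        x[i] <- x[i] + 1
        placed <- TRUE
        break
      }
    }
    if (!placed) fnafs_abort("apportionment stuck below total",
                             "fnafs_infeasible_error")
  }
  while (sum(x) > total) {
    trimmed <- FALSE
    for (i in rev(ord)) {
      if (x[i] > floors[i]) {
        x[i] <- x[i] - 1
        trimmed <- TRUE
        break
      }
    }
    if (!trimmed) fnafs_abort("apportionment stuck above total",
                              "fnafs_infeasible_error")
  }
  as.integer(x)
}

# Interleave `counts[k]` copies of level k as evenly as possible along a
# sequence of length sum(counts): each copy sits at quantile (i-0.5)/n_k and
# the merged order is the sort of those positions (ties by level order).
spread_levels <- function(levels, counts) {
  stopifnot(length(levels) == length(counts), is_count(counts))
  vals <- unlist(lapply(counts, function(n) if (n > 0) (seq_len(n) - 0.5) / n else numeric(0)))
  labs <- rep(levels, counts)
  idx <- rep(seq_along(levels), counts)
  labs[order(vals, idx)]
}
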