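# Shared fixtures and independent oracles used across the suite.

# Build a block of embryo records with uniform viability and optional
# endpoint flags (named list endpoint -> logical vector or scalar).
make_records <- function(n, material_id = "NP-1", concentration = 10,
                         alive_24hpf = TRUE, alive_120hpf = TRUE,
                         endpoints = list()) {
  d <- data.frame(
    material_id = rep(material_id, n), concentration = rep(concentration, n),
    well_id = sprintf("W%03d", seq_len(n)),
    alive_24hpf = rep_len(alive_24hpf, n),
    alive_120hpf = rep_len(alive_120hpf, n),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (e in names(endpoints)) d[[e]] <- rep_len(endpoints[[e]], n)
  d
}

# Random valid exposure group: arbitrary mix of dead-at-24, dead-by-120 and
# viable embryos with random endpoint flags on the survivors.
random_group <- function(n = sample(1:30, 1)) {
  fate <- sample(c("d24", "d120", "ok"), n, replace = TRUE)
  d <- make_records(n, alive_24hpf = fate != "d24", alive_120hpf = fate == "ok")
  for (e in ez_endpoints()) {
    d[[e]] <- fate == "ok" & stats::runif(n) < 0.2
  }
  d
}

# Independent per-embryo scoring oracle: 1.0 dead at 24 hpf, 0.95 dead by
# 120 hpf, else the sum of weights of observed endpoints; group score is the
# plain mean.
oracle_group_score <- function(records, weights = ez_weights()) {
  per <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    if (!r$alive_24hpf) return(1.0)
    if (!r$alive_120hpf) return(0.95)
    sum(unclass(weights)[ez_endpoints()][
      vapply(ez_endpoints(), function(e) isTRUE(r[[e]]), TRUE)])
  }, numeric(1))
  mean(per)
}

# Brute-force greedy Ward oracle: at every step compute the exact increase in
# within-cluster sum of squares for every cluster pair and merge the cheapest
# (scan order breaks ties). Returns the merge costs and the member sets
# merged at each step.
brute_ward <- function(x) {
  sse <- function(rows) {
    m <- x[rows, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  clusters <- lapply(seq_len(nrow(x)), identity)
  heights <- numeric(0)
  merged_sets <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bcost <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        cost <- sse(c(clusters[[i]], clusters[[j]])) -
          sse(clusters[[i]]) - sse(clusters[[j]])
        if (cost < bcost) { bcost <- cost; best <- c(i, j) }
      }
    }
    heights <- c(heights, bcost)
    new <- c(clusters[[best[1]]], clusters[[best[2]]])
    merged_sets <- c(merged_sets, list(sort(new)))
    clusters <- c(clusters[-best], list(new))
  }
  list(heights = heights, merged_sets = merged_sets)
}

# Member sets merged at each step of an hclust-style tree.
hclust_merged_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  expand <- function(code) {
    if (code < 0) return(-code)
    sets[[code]]
  }
  for (k in seq_len(nrow(hc$merge))) {
    sets[[k]] <- sort(c(expand(hc$merge[k, 1]), expand(hc$merge[k, 2])))
  }
  sets
}
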