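# Independent oracles, deliberately written as straight transcriptions of
# the model definitions and by brute force, not via the package code paths.

# decreasing form: p1 - (p2 L)^p3 - p4/(1 + ln(L/p5)^2); NA pair => term 0
oracle_dip <- function(p1, p2, p3, p4, p5, L) {
  power <- if (is.na(p2)) 0 else (p2 * L)^p3
  dip <- if (is.na(p4)) 0 else p4 / (1 + log(L / p5)^2)
  p1 - power - dip
}

# increasing form: (p1 + (p2 L)^p3) / (1 + (p4 L)^p5); NA pair => denom 1
oracle_overkill <- function(p1, p2, p3, p4, p5, L) {
  num <- p1 + if (is.na(p2)) 0 else (p2 * L)^p3
  den <- 1 + if (is.na(p4)) 0 else (p4 * L)^p5
  num / den
}

oracle_eval_row <- function(row, L) {
  if (row$damage_class %in% c("SB", "SSB")) {
    oracle_dip(row$p1, row$p2, row$p3, row$p4, row$p5, L)
  } else {
    oracle_overkill(row$p1, row$p2, row$p3, row$p4, row$p5, L)
  }
}

# dose-weighted mixed yield by direct summation
oracle_mixed <- function(doses, yields) sum(doses * yields) / sum(doses)

# --- exhaustive pairing oracle -------------------------------------------
# Enumerates ALL maximum-cardinality pairings of opposite-strand breaks
# within dsb_bp, by branching on the lowest unconsumed index.

oracle_all_max_pairings <- function(position, strand, dsb_bp) {
  n <- length(position)
  best_size <- -1L
  best <- list()
  recurse <- function(avail, pairs) {
    if (length(avail) == 0L) {
      size <- nrow(pairs)
      if (size > best_size) {
        best_size <<- size
        best <<- list(pairs)
      } else if (size == best_size) {
        best[[length(best) + 1L]] <<- pairs
      }
      return(invisible())
    }
    # upper bound prune: even pairing everything left cannot beat best
    if (nrow(pairs) + length(avail) %/% 2L < best_size) return(invisible())
    i <- avail[1]
    rest <- avail[-1]
    partners <- rest[strand[rest] != strand[i] &
                       abs(position[rest] - position[i]) <= dsb_bp]
    for (j in partners) {
      recurse(setdiff(rest, j), rbind(pairs, c(i, j)))
    }
    recurse(rest, pairs)  # leave i unpaired
  }
  recurse(seq_len(n), matrix(integer(0), ncol = 2))
  # deduplicate pairings (same pair set reached via different orders)
  keys <- vapply(best, function(p) {
    if (nrow(p) == 0L) return("")
    paste(sort(apply(p, 1, function(r) paste(sort(r), collapse = "-"))),
          collapse = ";")
  }, character(1))
  best[!duplicated(keys)]
}

# cluster/site tally for one pairing (independent reimplementation)
oracle_tally_for_pairing <- function(position, pairs, cluster_bp) {
  n_dsb <- nrow(pairs)
  if (n_dsb == 0L) {
    return(list(n_dsb = 0L, n_clusters = 0L, n_sites = 0L))
  }
  mid <- sort(floor((position[pairs[, 1]] + position[pairs[, 2]]) / 2))
  groups <- cumsum(c(TRUE, diff(mid) > cluster_bp))
  sizes <- as.integer(table(groups))
  list(n_dsb = n_dsb, n_clusters = sum(sizes >= 2L),
       n_sites = length(sizes))
}

# full oracle: max cardinality + the set of achievable tallies over all
# maximum pairings (different maximum pairings may legitimately differ in
# cluster structure)
oracle_classifier <- function(breaks, dsb_bp = 10, cluster_bp = 25) {
  key <- paste(breaks$position, breaks$strand)
  keep <- !duplicated(key)
  pos <- breaks$position[keep]
  str <- breaks$strand[keep]
  pairings <- oracle_all_max_pairings(pos, str, dsb_bp)
  tallies <- lapply(pairings, oracle_tally_for_pairing, position = pos,
                    cluster_bp = cluster_bp)
  n_dsb_max <- if (length(tallies)) tallies[[1]]$n_dsb else 0L
  list(n_dedup = length(pos), n_dsb_max = n_dsb_max,
       tallies = unique(lapply(tallies, function(t) {
         c(n_dsb = t$n_dsb, n_clusters = t$n_clusters,
           n_sites = t$n_sites)
       })))
}

# random dense break pattern for pairing-oracle comparisons:
# <= max_breaks breaks on a short span so every window is dense
random_dense_breaks <- function(seed, max_breaks = 12L, span = 60L) {
  set.seed(seed)
  n <- sample.int(max_breaks, 1L)
  data.frame(
    position = sample.int(span, n, replace = TRUE) - 1L,
    strand = sample(0:1, n, replace = TRUE),
    mechanism = sample(c("direct", "indirect"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

builtin_db <- function() load_params()
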