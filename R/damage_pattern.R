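#' Strand-break induction probabilities
#'
#' Direct effects: the probability that an energy deposition to a single
#' sugar-phosphate group breaks the backbone rises linearly from 0 at
#' 5 eV to 1 at 37.5 eV.  Indirect effects: a hydroxyl-radical attack on
#' the deoxyribose breaks the strand with probability 0.65.  No other
#' species induce strand breaks.
#'
#' @param energy_ev Deposited energy in eV, >= 0 (vectorized).
#' @return Breakage probability in \[0, 1\].
#' @examples
#' direct_break_prob(c(5, 21.25, 37.5))
#' indirect_break_prob()
#' @export
direct_break_prob <- function(energy_ev) {
  if (any(energy_ev < 0)) stop_validation("`energy_ev` must be >= 0")
  pmin(1, pmax(0, (energy_ev - 5) / 32.5))
}

#' @rdname direct_break_prob
#' @export
indirect_break_prob <- function() 0.65

#' Construct a deposition-event table
#'
#' @param position Integer bp coordinates (>= 0) of the targeted
#'   sugar-phosphate groups.
#' @param strand Strand index, 0 or 1.
#' @param kind `"ENERGY"` (direct energy deposition) or `"OH_ATTACK"`
#'   (hydroxyl-radical attack).
#' @param energy_ev Deposited energy in eV for `ENERGY` events (> 0);
#'   `NA` for `OH_ATTACK`.
#' @return A validated data.frame of deposition events.
#' @export
deposition_events <- function(position, strand, kind, energy_ev = NA) {
  kind <- toupper(kind)
  n <- length(position)
  ev <- data.frame(position = as.integer(position),
                   strand = as.integer(strand),
                   kind = rep_len(kind, n),
                   energy_ev = rep_len(as.numeric(energy_ev), n),
                   stringsAsFactors = FALSE)
  if (any(ev$position < 0)) stop_validation("positions must be >= 0")
  if (!all(ev$strand %in% c(0L, 1L))) {
    stop_validation("strand must be 0 or 1")
  }
  if (!all(ev$kind %in% c("ENERGY", "OH_ATTACK"))) {
    stop_validation("kind must be ENERGY or OH_ATTACK")
  }
  bad <- ev$kind == "ENERGY" & (is.na(ev$energy_ev) | ev$energy_ev <= 0)
  if (any(bad)) {
    stop_validation("ENERGY events need energy_ev > 0")
  }
  ev
}

#' Sample strand breaks from deposition events
#'
#' Each `ENERGY` event induces a DIRECT break with probability
#' [direct_break_prob()] of its energy; each `OH_ATTACK` induces an
#' INDIRECT break with probability 0.65.  Duplicates at one
#' (position, strand) are retained at this stage with both mechanisms
#' recorded; [classify_breaks()] deduplicates them.
#'
#' @param events A data.frame from [deposition_events()].
#' @param seed Integer seed for reproducibility.
#' @return A data.frame with columns `position`, `strand`, `mechanism`
#'   (`"direct"` / `"indirect"`).
#' @export
sample_breaks <- function(events, seed = NULL) {
  p <- numeric(nrow(events))
  en <- events$kind == "ENERGY"
  p[en] <- direct_break_prob(events$energy_ev[en])
  p[!en] <- indirect_break_prob()
  hit <- with_seed(seed, stats::runif(nrow(events)) < p)
  data.frame(
    position = events$position[hit],
    strand = events$strand[hit],
    mechanism = ifelse(events$kind[hit] == "ENERGY", "direct", "indirect"),
    stringsAsFactors = FALSE)
}

#' Read a break list
#'
#' TSV with columns `position_bp`, `strand` (0/1), `mechanism`
#' (direct/indirect); `#` comment lines are ignored.
#'
#' @param path TSV file path.
#' @return A break data.frame with columns `position`, `strand`,
#'   `mechanism`.
#' @export
read_breaks <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("break file not found: %s", path))
  x <- utils::read.delim(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("position_bp", "strand", "mechanism")
  if (!all(need %in% names(x))) {
    stop_validation(paste("break TSV must have columns:",
                          paste(need, collapse = ", ")))
  }
  data.frame(position = as.integer(x$position_bp),
             strand = as.integer(x$strand),
             mechanism = tolower(x$mechanism), stringsAsFactors = FALSE)
}

# deduplicate breaks per (position, strand); a site broken both directly
# and indirectly is retained once with both mechanisms recorded
dedup_breaks <- function(breaks) {
  key <- paste(breaks$position, breaks$strand)
  direct <- tapply(breaks$mechanism == "direct", key, any)
  indirect <- tapply(breaks$mechanism == "indirect", key, any)
  first <- !duplicated(key)
  d <- data.frame(position = breaks$position[first],
                  strand = breaks$strand[first],
                  stringsAsFactors = FALSE)
  k <- paste(d$position, d$strand)
  d$direct <- as.logical(direct[k])
  d$indirect <- as.logical(indirect[k])
  d[order(d$position, d$strand), , drop = FALSE]
}

# greedy pairing: repeatedly take the leftmost unconsumed break and pair
# it with the nearest unconsumed opposite-strand break within dsb_bp
# (ties to the lower position); unpaired breaks become SSB
pair_dsb <- function(d, dsb_bp) {
  n <- nrow(d)
  consumed <- rep(FALSE, n)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n)) {
    if (consumed[i]) next
    cand <- which(!consumed & d$strand != d$strand[i] &
                    abs(d$position - d$position[i]) <= dsb_bp)
    cand <- setdiff(cand, i)
    if (length(cand) > 0L) {
      dist <- abs(d$position[cand] - d$position[i])
      j <- cand[order(dist, d$position[cand])][1]
      consumed[c(i, j)] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
    # else: leave i unconsumed; it can no longer be paired because all
    # later breaks are farther right and earlier ones are consumed or
    # incompatible -- it is an SSB
  }
  list(pairs = pairs, ssb = which(!matrix_rows_consumed(pairs, n)))
}

matrix_rows_consumed <- function(pairs, n) {
  consumed <- rep(FALSE, n)
  if (nrow(pairs) > 0L) consumed[as.vector(pairs)] <- TRUE
  consumed
}

# transitive (single-linkage) chaining of DSB midpoints within cluster_bp
cluster_dsb <- function(midpoints, cluster_bp) {
  if (length(midpoints) == 0L) return(integer(0))
  o <- order(midpoints)
  gap_new <- c(TRUE, diff(midpoints[o]) > cluster_bp)
  grp_sorted <- cumsum(gap_new)
  grp <- integer(length(midpoints))
  grp[o] <- grp_sorted
  grp
}

#' Classify a strand-break list
#'
#' Applies the standard damage classification: after deduplication per
#' (position, strand), opposite-strand breaks within `dsb_bp` (default
#' 10 bp, inclusive) are paired into DSBs by a greedy left-to-right scan
#' (leftmost unconsumed break first, nearest opposite-strand partner,
#' each break consumed at most once); DSBs whose midpoints lie within
#' `cluster_bp` (default 25 bp, inclusive) of each other are chained
#' transitively into clusters; a DSB site is an isolated DSB or one whole
#' cluster; unpaired breaks are SSBs.
#'
#' Channel sub-tallies: a break induced both directly and indirectly
#' counts once in the totals but contributes to both the direct and
#' indirect SB/SSB sub-tallies.  A DSB is `direct` if both breaks are
#' direct-only, `indirect` if both are indirect-only, and `hybrid`
#' otherwise.
#'
#' @param breaks A data.frame with columns `position` (bp, >= 0),
#'   `strand` (0/1), `mechanism` (`"direct"`/`"indirect"`).
#' @param dsb_bp Maximum opposite-strand separation of a DSB in bp
#'   (default 10).
#' @param cluster_bp Maximum centre-to-centre DSB separation within a
#'   cluster in bp (default 25).
#' @return A list of class `"damage_tally"` with counts `n_sb_total`,
#'   `n_ssb`, `n_dsb`, `n_dsb_clusters`, `n_dsb_sites`,
#'   `n_dsb_per_cluster_mean`, channel sub-tallies `ssb_channels`
#'   (direct/indirect) and `dsb_channels` (direct/indirect/hybrid), and
#'   the DSB midpoint positions `dsb_positions`.
#' @examples
#' b <- data.frame(position = c(100, 105), strand = c(0, 1),
#'                 mechanism = "direct")
#' classify_breaks(b)
#' @export
classify_breaks <- function(breaks, dsb_bp = 10, cluster_bp = 25) {
  if (dsb_bp < 0 || cluster_bp < 0) {
    stop_validation("`dsb_bp` and `cluster_bp` must be >= 0")
  }
  if (nrow(breaks) == 0L) {
    return(empty_tally())
  }
  if (any(breaks$position < 0)) stop_validation("positions must be >= 0")
  if (!all(breaks$strand %in% c(0L, 1L))) {
    stop_validation("strand must be 0 or 1")
  }
  if (!all(breaks$mechanism %in% c("direct", "indirect"))) {
    stop_validation("mechanism must be 'direct' or 'indirect'")
  }
  d <- dedup_breaks(breaks)
  pr <- pair_dsb(d, dsb_bp)
  pairs <- pr$pairs
  n_dsb <- nrow(pairs)
  ssb_idx <- pr$ssb

  dsb_pos <- if (n_dsb > 0L) {
    as.integer(floor((d$position[pairs[, 1]] + d$position[pairs[, 2]]) / 2))
  } else {
    integer(0)
  }
  grp <- cluster_dsb(dsb_pos, cluster_bp)
  sizes <- if (n_dsb > 0L) as.integer(table(grp)) else integer(0)
  n_clusters <- sum(sizes >= 2L)
  n_sites <- length(sizes)

  dsb_channel <- if (n_dsb > 0L) {
    vapply(seq_len(n_dsb), function(k) {
      b1 <- d[pairs[k, 1], ]; b2 <- d[pairs[k, 2], ]
      pure_dir <- b1$direct & !b1$indirect & b2$direct & !b2$indirect
      pure_ind <- b1$indirect & !b1$direct & b2$indirect & !b2$direct
      if (pure_dir) "direct" else if (pure_ind) "indirect" else "hybrid"
    }, character(1))
  } else {
    character(0)
  }

  structure(list(
    n_sb_total = nrow(d),
    n_ssb = length(ssb_idx),
    n_dsb = n_dsb,
    n_dsb_clusters = n_clusters,
    n_dsb_sites = n_sites,
    n_dsb_per_cluster_mean =
      if (n_clusters > 0L) mean(sizes[sizes >= 2L]) else NA_real_,
    sb_channels = c(direct = sum(d$direct), indirect = sum(d$indirect)),
    ssb_channels = c(direct = sum(d$direct[ssb_idx]),
                     indirect = sum(d$indirect[ssb_idx])),
    dsb_channels = c(direct = sum(dsb_channel == "direct"),
                     indirect = sum(dsb_channel == "indirect"),
                     hybrid = sum(dsb_channel == "hybrid")),
    dsb_positions = dsb_pos), class = "damage_tally")
}

empty_tally <- function() {
  structure(list(
    n_sb_total = 0L, n_ssb = 0L, n_dsb = 0L, n_dsb_clusters = 0L,
    n_dsb_sites = 0L, n_dsb_per_cluster_mean = NA_real_,
    sb_channels = c(direct = 0L, indirect = 0L),
    ssb_channels = c(direct = 0L, indirect = 0L),
    dsb_channels = c(direct = 0L, indirect = 0L, hybrid = 0L),
    dsb_positions = integer(0)), class = "damage_tally")
}

#' @export
print.damage_tally <- function(x, ...) {
  cat("<damage_tally>\n")
  cat(sprintf("  SB (deduplicated): %d  SSB: %d  DSB: %d\n",
              x$n_sb_total, x$n_ssb, x$n_dsb))
  cat(sprintf("  DSB clusters: %d  DSB sites: %d  mean DSB/cluster: %s\n",
              x$n_dsb_clusters, x$n_dsb_sites,
              ifelse(is.na(x$n_dsb_per_cluster_mean), "-",
                     format(x$n_dsb_per_cluster_mean))))
  cat(sprintf("  DSB channels: direct %d, indirect %d, hybrid %d\n",
              x$dsb_channels[["direct"]], x$dsb_channels[["indirect"]],
              x$dsb_channels[["hybrid"]]))
  invisible(x)
}

#' Generate a synthetic track-like break pattern
#'
#' Fixture generator for classifier studies: each simulated track
#' deposits a cluster of breaks around a uniformly placed centre, with
#' within-cluster displacements drawn from a rounded normal of scale
#' `clustering_scale` (bp).  The number of breaks per track is Poisson.
#' Strand is fair-coin; the mechanism is direct with probability
#' `direct_fraction` (default 0.38, the low-LET direct share of strand
#' breakage, 64 of 170 per Gy per Gbp).
#'
#' @param n_tracks Number of tracks.
#' @param breaks_per_track Mean (Poisson) number of breaks per track.
#' @param clustering_scale Within-track displacement scale in bp; large
#'   values approach a uniform (sparse) pattern.
#' @param span Genomic span in bp; positions are clipped to `[0, span]`.
#' @param direct_fraction Probability that a break is direct.
#' @param seed Integer seed.
#' @return A break data.frame as accepted by [classify_breaks()].
#' @export
generate_break_pattern <- function(n_tracks, breaks_per_track = 2,
                                   clustering_scale = 5, span = 1e4,
                                   direct_fraction = 0.38, seed = NULL) {
  if (span <= 0) stop_validation("`span` must be > 0")
  with_seed(seed, {
    nb <- stats::rpois(n_tracks, breaks_per_track)
    centre <- stats::runif(n_tracks, 0, span)
    pos <- integer(0); str <- integer(0)
    for (t in seq_len(n_tracks)) {
      if (nb[t] == 0L) next
      p <- round(centre[t] + stats::rnorm(nb[t], sd = clustering_scale))
      p <- pmin(pmax(p, 0), floor(span))
      pos <- c(pos, as.integer(p))
      str <- c(str, stats::rbinom(nb[t], 1L, 0.5))
    }
    mech <- ifelse(stats::runif(length(pos)) < direct_fraction,
                   "direct", "indirect")
    data.frame(position = pos, strand = str, mechanism = mech,
               stringsAsFactors = FALSE)
  })
}
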