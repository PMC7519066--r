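#' Analytical LET-yield model forms
#'
#' Two functional forms represent the LET dependence of simulated DNA
#' damage yields (yield in Gy^-1 Gbp^-1, LET `L` in keV/um):
#'
#' * **Dip form** (SB, SSB; decreasing):
#'   \deqn{Y(L) = p_1 - (p_2 L)^{p_3} - p_4 / (1 + \ln^2(L/p_5))}
#'   a power-law decrease from the low-LET plateau `p1`, with a
#'   Gaussian-bell dip on the log-LET scale (depth `p4`, centre `p5`)
#'   representing the mild 3--7 % dip simulated at 5--20 keV/um.
#' * **Overkill form** (DSB, DSB clusters, DSB sites; increasing):
#'   \deqn{Y(L) = (p_1 + (p_2 L)^{p_3}) / (1 + (p_4 L)^{p_5})}
#'   a power-law increase modulated by a logistic denominator that
#'   reproduces the overkill-driven decline above ~100 keV/um.
#'
#' Omitted terms (`NA` parameter pairs) contribute nothing: an absent
#' dip/overkill term, and for a few constant-with-dip direct-SB fits an
#' absent power-law term.  The logarithm is natural.
#'
#' @param p Named numeric vector `c(p1, p2, p3, p4, p5)`; `NA` marks
#'   omitted terms.
#' @param let LET values in keV/um, all > 0.
#' @return Numeric vector of yields (raw model values, possibly negative
#'   for the dip form far outside the fitted range).
#' @name model_forms
NULL

#' @rdname model_forms
#' @export
yield_dip <- function(p, let) {
  stopifnot(all(let > 0))
  y <- rep(p[["p1"]], length(let))
  if (!is.na(p[["p2"]])) y <- y - (p[["p2"]] * let)^p[["p3"]]
  if (!is.na(p[["p4"]])) {
    y <- y - p[["p4"]] / (1 + log(let / p[["p5"]])^2)
  }
  unname(y)
}

#' @rdname model_forms
#' @export
yield_overkill <- function(p, let) {
  stopifnot(all(let > 0))
  num <- p[["p1"]]
  if (!is.na(p[["p2"]])) num <- num + (p[["p2"]] * let)^p[["p3"]]
  den <- if (!is.na(p[["p4"]])) 1 + (p[["p4"]] * let)^p[["p5"]] else 1
  unname(num / den)
}

eval_form <- function(form, p, let) {
  switch(form,
         powerlaw_dip      = yield_dip(p, let),
         powerlaw_overkill = yield_overkill(p, let),
         stop_validation(sprintf("unknown model form '%s'", form)))
}

#' Default LET validity windows
#'
#' The analytical fits should not be extrapolated outside the LET range
#' spanned by the underlying simulation points.  The source does not
#' tabulate per-ion ranges, so the package uses documented approximations:
#' `let_min` 0.2 keV/um for all ions and `let_max` rising with atomic
#' number from 100 keV/um (H) to 600 keV/um (Ne).  The window gates a
#' warning flag only, never an error.
#'
#' @param ion Ion symbol.
#' @return Numeric `c(let_min, let_max)` in keV/um.
#' @export
validity_window <- function(ion) {
  ion <- as_ion(ion)
  let_max <- c(H = 100, He = 160, Li = 220, Be = 280, B = 340,
               C = 400, N = 460, O = 520, Ne = 600)
  c(let_min = 0.2, let_max = unname(let_max[[ion]]))
}

#' Evaluate a damage-yield model at given LET
#'
#' Evaluates the analytical yield model of a parameter set at one or more
#' LET values.  `let = 0` is accepted and returns the analytic low-LET
#' limit `p1` (both forms tend to `p1` as LET tends to 0; the dip form is
#' singular at 0 and is not evaluated there directly).
#'
#' The dip form can go negative far outside the fitted LET range; by
#' default the raw model value is returned together with flags, and
#' `clamp = TRUE` opts into truncation at 0.
#'
#' @param params A `"yield_params"` object from [query_params()].
#' @param let Numeric LET values in keV/um, all >= 0.
#' @param clamp Truncate negative dip-form values at 0 (default `FALSE`).
#' @param details If `TRUE` return a data.frame with columns `let`,
#'   `value`, `in_validity_range`, `clamped`; otherwise (default) a plain
#'   numeric vector.
#' @param window Validity window `c(let_min, let_max)`; defaults to
#'   [validity_window()] for the parameter set's ion.
#' @return Numeric vector of yields in Gy^-1 Gbp^-1, or a data.frame when
#'   `details = TRUE`.
#' @examples
#' db <- load_params()
#' eval_yield(query_params(db, "H", "DSB"), let = 10)
#' @export
eval_yield <- function(params, let, clamp = FALSE, details = FALSE,
                       window = NULL) {
  stopifnot(inherits(params, "yield_params"))
  if (!is.numeric(let) || any(is.na(let)) || any(let < 0)) {
    stop_validation("`let` must be numeric and >= 0 (keV/um)")
  }
  if (is.null(window)) window <- validity_window(params$ion)
  value <- numeric(length(let))
  pos <- let > 0
  value[pos] <- eval_form(params$form, params$p, let[pos])
  value[!pos] <- params$p[["p1"]]
  clamped <- rep(FALSE, length(let))
  if (clamp) {
    clamped <- value < 0
    value[clamped] <- 0
  }
  in_range <- let >= window[[1]] & let <= window[[2]]
  if (details) {
    data.frame(let = let, value = value,
               in_validity_range = in_range, clamped = clamped)
  } else {
    value
  }
}

#' Low-LET yield limit
#'
#' The LET -> 0 limit of both model forms is the universal parameter `p1`:
#' the power-law term vanishes, the dip term vanishes (its log-scale
#' denominator diverges) and the overkill denominator tends to 1.
#'
#' @param params A `"yield_params"` object.
#' @return The low-LET yield `p1` in Gy^-1 Gbp^-1.
#' @export
low_let_limit <- function(params) {
  stopifnot(inherits(params, "yield_params"))
  unname(params$p[["p1"]])
}

#' Locate the peak yield of an increasing-form model
#'
#' Maximizes the overkill-form model over an LET window: a 1000-point
#' log-spaced grid scan (ties broken to the lowest LET) refined by bounded
#' scalar optimization in the bracketing grid interval.  If the maximum
#' sits at a window edge (e.g. a monotone model without an overkill term),
#' the `at_boundary` flag is set and no refinement is attempted beyond the
#' edge.
#'
#' @param params A `"yield_params"` object with form `"powerlaw_overkill"`.
#' @param window Numeric `c(let_min, let_max)` in keV/um, 0 < min < max.
#' @param tol Relative LET tolerance of the refinement (default 1e-8).
#' @return A list with `let` (keV/um), `yield` (Gy^-1 Gbp^-1) and
#'   `at_boundary` (logical).
#' @examples
#' db <- load_params()
#' peak_yield(query_params(db, "C", "DSB_SITE"), c(1, 300))
#' @export
peak_yield <- function(params, window, tol = 1e-8) {
  stopifnot(inherits(params, "yield_params"))
  if (params$form != "powerlaw_overkill") {
    stop_validation("peak_yield() requires the increasing (overkill) model form")
  }
  if (length(window) != 2L || !all(is.finite(window)) ||
      window[1] <= 0 || window[2] <= window[1]) {
    stop_validation("`window` must be c(let_min, let_max) with 0 < min < max")
  }
  grid <- exp(seq(log(window[1]), log(window[2]), length.out = 1000L))
  grid[1] <- window[1]
  grid[length(grid)] <- window[2]
  vals <- eval_form(params$form, params$p, grid)
  i <- which.max(vals)  # first occurrence: lowest-LET tie-break
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  at_boundary <- i == 1L || i == length(grid)
  if (lo < hi) {
    opt <- stats::optimize(function(L) eval_form(params$form, params$p, L),
                           interval = c(lo, hi), maximum = TRUE,
                           tol = tol * (hi - lo) + .Machine$double.eps)
    if (opt$objective >= vals[i]) {
      best_let <- opt$maximum
      best_val <- opt$objective
    } else {
      best_let <- grid[i]
      best_val <- vals[i]
    }
  } else {
    best_let <- grid[i]
    best_val <- vals[i]
  }
  if (at_boundary) {
    # report the window edge itself
    best_let <- grid[i]
    best_val <- vals[i]
  }
  list(let = best_let, yield = best_val, at_boundary = at_boundary)
}

#' Tabulate yields over an LET grid
#'
#' @param db A `"yield_param_db"` data.frame.
#' @param specs A data.frame with columns `ion`, `damage_class` and
#'   optionally `channel` (default TOTAL), one row per requested model.
#' @param let Numeric LET grid in keV/um (may be empty).
#' @param clamp Passed to [eval_yield()].
#' @return A data.frame with column `let` and one column per spec, named
#'   `<class>.<ion>.<channel>`; values identical to pointwise
#'   [eval_yield()] calls.
#' @export
yield_table <- function(db, specs, let, clamp = FALSE) {
  if (is.null(specs$channel)) specs$channel <- "TOTAL"
  out <- data.frame(let = as.numeric(let))
  for (i in seq_len(nrow(specs))) {
    par <- query_params(db, specs$ion[i], specs$damage_class[i],
                        specs$channel[i])
    nm <- paste(par$damage_class, par$ion, par$channel, sep = ".")
    out[[nm]] <- if (length(let) > 0L) {
      eval_yield(par, let, clamp = clamp)
    } else {
      numeric(0)
    }
  }
  out
}

#' RBE reference policy
#'
#' The reference radiation for RBE is low-LET hydrogen of the same damage
#' class and channel (its damage induction matches reference photon
#' irradiation).  The default policy uses the hydrogen low-LET limit `p1`;
#' alternatively the hydrogen yield at a stated LET can serve as
#' reference.
#'
#' @param type `"low_let"` (default) or `"at_let"`.
#' @param ion Reference ion symbol (default `"H"`).
#' @param let Reference LET in keV/um, required for `type = "at_let"`.
#' @return A list describing the policy, for [rbe()] and [mixed_rbe()].
#' @export
rbe_reference <- function(type = c("low_let", "at_let"), ion = "H",
                          let = NULL) {
  type <- match.arg(type)
  if (type == "at_let" && (is.null(let) || !is.numeric(let) || let <= 0)) {
    stop_validation("reference type 'at_let' requires a positive `let`")
  }
  list(type = type, ion = as_ion(ion), let = let)
}

reference_yield <- function(db, damage_class, channel, reference) {
  par <- query_params(db, reference$ion, damage_class, channel)
  ref <- if (reference$type == "low_let") {
    low_let_limit(par)
  } else {
    eval_yield(par, reference$let)
  }
  if (!is.finite(ref) || ref == 0) {
    stop_validation("RBE reference yield is zero or non-finite")
  }
  ref
}

#' Relative biological effectiveness for damage induction
#'
#' Damage induction is linear in dose, so the RBE (formally a ratio of
#' doses producing equal effect) reduces to the ratio of damage yields at
#' the same dose: the yield of the given radiation divided by the
#' reference yield.
#'
#' @param db A `"yield_param_db"` data.frame.
#' @param ion Ion symbol.
#' @param damage_class Damage class.
#' @param let LET in keV/um (vectorized).
#' @param channel Effect channel (default TOTAL).
#' @param reference A policy from [rbe_reference()].
#' @return Dimensionless RBE values.
#' @examples
#' db <- load_params()
#' rbe(db, "C", "DSB", let = 150)
#' @export
rbe <- function(db, ion, damage_class, let, channel = "TOTAL",
                reference = rbe_reference()) {
  par <- query_params(db, ion, damage_class, channel)
  eval_yield(par, let) / reference_yield(db, par$damage_class,
                                         par$channel, reference)
}

#' Expected damage count per cell
#'
#' Converts a per-dose, per-Gbp yield into an expected count per cell:
#' `yield * dose * genome_gbp`.  The default genome size is the 6.6 Gbp of
#' the simulated human (G0/G1) nucleus model.  Damage induction is linear
#' in dose at least up to doses of order 100--1000 Gy; above 100 Gy a
#' warning is emitted.
#'
#' @param yield Yield in Gy^-1 Gbp^-1.
#' @param dose Absorbed dose in Gy, >= 0.
#' @param genome_gbp Genome size in Gbp (default 6.6).
#' @return Expected number of damage events per cell.
#' @examples
#' per_cell_yield(6.8, dose = 1)  # 44.88 DSB per cell
#' @export
per_cell_yield <- function(yield, dose, genome_gbp = 6.6) {
  if (any(dose < 0)) stop_validation("`dose` must be >= 0")
  if (any(genome_gbp <= 0)) stop_validation("`genome_gbp` must be > 0")
  if (any(dose > 100)) {
    warning("dose exceeds 100 Gy: damage additivity (linearity in dose) ",
            "may break down between 100 and 1000 Gy", call. = FALSE)
  }
  yield * dose * genome_gbp
}
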