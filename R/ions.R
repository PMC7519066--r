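#' Supported ion species
#'
#' The damage-yield database covers fully stripped light ions from hydrogen
#' to neon.  Symbol, atomic number and mass number form a fixed bijection:
#' \eqn{^{1}}H, \eqn{^{4}}He, \eqn{^{7}}Li, \eqn{^{9}}Be, \eqn{^{11}}B,
#' \eqn{^{12}}C, \eqn{^{14}}N, \eqn{^{16}}O, \eqn{^{20}}Ne.
#'
#' @return A data.frame with columns `symbol`, `atomic_number`,
#'   `mass_number`, one row per supported ion, ordered by atomic number.
#' @examples
#' ion_table()
#' @export
ion_table <- function() {
  data.frame(
    symbol        = c("H", "He", "Li", "Be", "B", "C", "N", "O", "Ne"),
    atomic_number = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 10L),
    mass_number   = c(1L, 4L, 7L, 9L, 11L, 12L, 14L, 16L, 20L),
    stringsAsFactors = FALSE
  )
}

#' @rdname ion_table
#' @format NULL
#' @usage NULL
#' @export
ION_SYMBOLS <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "Ne")

#' @rdname damage_vocab
#' @format NULL
#' @usage NULL
#' @export
DAMAGE_CLASSES <- c("SB", "SSB", "DSB", "DSB_CLUSTER", "DSB_SITE")

#' Damage classification vocabulary
#'
#' Damage classes scored by the underlying track-structure simulations:
#' strand breaks (SB, either strand), single-strand breaks (SSB, an SB not
#' part of a DSB), double-strand breaks (DSB, SB on both strands within
#' 10 bp), DSB clusters (two or more DSB within 25 bp) and DSB sites
#' (an isolated DSB or one whole cluster, counted once).  Each class is
#' modelled separately for the `TOTAL`, purely `DIRECT` (energy deposition
#' to the sugar-phosphate backbone) and purely `INDIRECT` (hydroxyl-radical
#' attack) effect channels; totals are not the sum of the two separate
#' channels because coincident and hybrid events are scored once.
#'
#' @name damage_vocab
#' @aliases DAMAGE_CLASSES CHANNELS
NULL

#' @rdname damage_vocab
#' @format NULL
#' @usage NULL
#' @export
CHANNELS <- c("TOTAL", "DIRECT", "INDIRECT")

# normalize and validate an ion symbol (case-insensitive)
as_ion <- function(ion) {
  if (length(ion) != 1L || is.na(ion)) {
    stop_validation("`ion` must be a single ion symbol")
  }
  hit <- match(toupper(as.character(ion)),
               toupper(ION_SYMBOLS))
  if (is.na(hit)) {
    stop_validation(sprintf(
      "unknown ion symbol '%s'; valid symbols: %s",
      ion, paste(ION_SYMBOLS, collapse = ", ")))
  }
  ION_SYMBOLS[hit]
}

as_damage_class <- function(damage_class) {
  if (length(damage_class) != 1L || is.na(damage_class)) {
    stop_validation("`damage_class` must be a single damage class")
  }
  key <- chartr("-", "_", toupper(as.character(damage_class)))
  # accept the lowercase CLI spellings dsb_cluster / dsb_site etc.
  hit <- match(key, DAMAGE_CLASSES)
  if (is.na(hit)) {
    stop_validation(sprintf(
      "unknown damage class '%s'; valid classes: %s",
      damage_class, paste(DAMAGE_CLASSES, collapse = ", ")))
  }
  DAMAGE_CLASSES[hit]
}

as_channel <- function(channel) {
  if (length(channel) != 1L || is.na(channel)) {
    stop_validation("`channel` must be a single effect channel")
  }
  hit <- match(toupper(as.character(channel)), CHANNELS)
  if (is.na(hit)) {
    stop_validation(sprintf(
      "unknown channel '%s'; valid channels: %s",
      channel, paste(CHANNELS, collapse = ", ")))
  }
  CHANNELS[hit]
}

#' Model form associated with a damage class
#'
#' SB and SSB yields decrease with LET and use the power-law-with-dip form
#' (`"powerlaw_dip"`); DSB, DSB-cluster and DSB-site yields increase with
#' LET, modulated by a logistic overkill denominator
#' (`"powerlaw_overkill"`).
#'
#' @param damage_class One of `DAMAGE_CLASSES`.
#' @return `"powerlaw_dip"` or `"powerlaw_overkill"`.
#' @export
model_form <- function(damage_class) {
  damage_class <- as_damage_class(damage_class)
  if (damage_class %in% c("SB", "SSB")) "powerlaw_dip" else "powerlaw_overkill"
}

# ---- structured error conditions (CLI maps these to exit codes) ----------

stop_validation <- function(msg, data = NULL) {
  cond <- structure(
    class = c("iondamage_validation_error", "iondamage_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1), data = data))
  stop(cond)
}

stop_io <- function(msg) {
  cond <- structure(
    class = c("iondamage_io_error", "iondamage_error", "error", "condition"),
    list(message = msg, call = sys.call(-1)))
  stop(cond)
}
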