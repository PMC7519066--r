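#' Load a damage-yield parameter database
#'
#' Reads a collection of fitted yield-model parameter sets, either the
#' built-in database shipped with the package (135 sets: 9 ions x 5 damage
#' classes x 3 effect channels) or a user file in the documented CSV or
#' JSON schema.
#'
#' The CSV schema has one header row and columns
#' `damage_class, ion, channel, p1, p2, p3, p4, p5`; absent model terms are
#' the literal token `NA`.  The JSON schema is an array of objects with the
#' same keys (absent terms are `null`).  `p1` is the universal low-LET
#' yield in Gy^-1 Gbp^-1, `p2` (um/keV) and `p3` (dimensionless) scale the
#' power-law term; in the SB/SSB (dip) form `p4` is the dip depth in
#' Gy^-1 Gbp^-1 and `p5` the dip-centre LET in keV/um, in the DSB
#' (overkill) form `p4` is an inverse-LET overkill scale in um/keV and
#' `p5` a dimensionless overkill power.  A term's two parameters are
#' present or absent together.
#'
#' @param source `"builtin"` for the packaged database, or a path to a
#'   `.csv` or `.json` file.
#' @return A data.frame of class `"yield_param_db"` with columns
#'   `damage_class`, `ion`, `channel`, `form`, `p1`..`p5`.
#' @seealso [query_params()], [validate_db()], [save_params()]
#' @examples
#' db <- load_params()
#' query_params(db, "H", "DSB", "TOTAL")
#' @export
load_params <- function(source = "builtin") {
  if (identical(source, "builtin")) {
    path <- system.file("extdata", "yield_params.csv",
                        package = "iondamage", mustWork = TRUE)
    db <- read_params_csv(path)
  } else {
    if (!file.exists(source)) {
      stop_io(sprintf("parameter file not found: %s", source))
    }
    db <- switch(tolower(tools::file_ext(source)),
      csv  = read_params_csv(source),
      json = read_params_json(source),
      stop_validation("parameter file must be .csv or .json"))
  }
  db <- normalize_param_db(db)
  issues <- validate_db(db, completeness = identical(source, "builtin"))
  hard <- issues[issues$finding != "completeness" |
                   identical(source, "builtin"), , drop = FALSE]
  if (nrow(hard) > 0L) {
    stop_validation(
      paste0("invalid parameter database:\n",
             paste0("  - ", hard$message, collapse = "\n")),
      data = hard)
  }
  db
}

read_params_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = c(damage_class = "character",
                                 ion = "character", channel = "character"))
}

read_params_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  as.data.frame(x, stringsAsFactors = FALSE)
}

normalize_param_db <- function(db) {
  need <- c("damage_class", "ion", "channel", "p1", "p2", "p3", "p4", "p5")
  miss <- setdiff(need, names(db))
  if (length(miss) > 0L) {
    stop_validation(paste("parameter table lacks column(s):",
                          paste(miss, collapse = ", ")))
  }
  db <- db[, need]
  for (p in c("p1", "p2", "p3", "p4", "p5")) {
    if (!is.numeric(db[[p]])) {
      bad <- !is.na(db[[p]]) & is.na(suppressWarnings(as.numeric(db[[p]])))
      if (any(bad)) {
        stop_validation(sprintf(
          "malformed number in column %s, e.g. (%s, %s, %s): '%s'",
          p, db$damage_class[bad][1], db$ion[bad][1], db$channel[bad][1],
          db[[p]][bad][1]))
      }
      db[[p]] <- suppressWarnings(as.numeric(db[[p]]))
    }
  }
  db$form <- ifelse(db$damage_class %in% c("SB", "SSB"),
                    "powerlaw_dip", "powerlaw_overkill")
  db <- db[, c("damage_class", "ion", "channel", "form",
               "p1", "p2", "p3", "p4", "p5")]
  class(db) <- c("yield_param_db", "data.frame")
  db
}

#' Validate a parameter database
#'
#' Checks completeness (every supported ion x damage class x channel triple
#' present exactly once), positivity of all present parameters, pairing of
#' optional terms (`p2`/`p3` together, `p4`/`p5` together), vocabulary, and
#' the universal low-LET yield constraint (within each damage class and
#' channel, all ions share one `p1`).
#'
#' @param db A `"yield_param_db"` data.frame, e.g. from [load_params()].
#' @param completeness Require all 135 triples (default `TRUE`).
#' @return A data.frame report with columns `finding`, `damage_class`,
#'   `ion`, `channel`, `message`; zero rows if and only if the database is
#'   valid.
#' @export
validate_db <- function(db, completeness = TRUE) {
  rep0 <- data.frame(finding = character(), damage_class = character(),
                     ion = character(), channel = character(),
                     message = character(), stringsAsFactors = FALSE)
  add <- function(rep, finding, cls, ion, ch, msg) {
    rbind(rep, data.frame(finding = finding, damage_class = cls, ion = ion,
                          channel = ch, message = msg,
                          stringsAsFactors = FALSE))
  }
  rep <- rep0

  bad_ion <- !(db$ion %in% ION_SYMBOLS)
  for (i in which(bad_ion)) {
    rep <- add(rep, "vocabulary", db$damage_class[i], db$ion[i],
               db$channel[i], sprintf("unknown ion '%s'", db$ion[i]))
  }
  bad_cls <- !(db$damage_class %in% DAMAGE_CLASSES)
  for (i in which(bad_cls)) {
    rep <- add(rep, "vocabulary", db$damage_class[i], db$ion[i],
               db$channel[i],
               sprintf("unknown damage class '%s'", db$damage_class[i]))
  }
  bad_ch <- !(db$channel %in% CHANNELS)
  for (i in which(bad_ch)) {
    rep <- add(rep, "vocabulary", db$damage_class[i], db$ion[i],
               db$channel[i], sprintf("unknown channel '%s'", db$channel[i]))
  }

  key <- paste(db$damage_class, db$ion, db$channel)
  dup <- duplicated(key)
  for (i in which(dup)) {
    rep <- add(rep, "duplicate", db$damage_class[i], db$ion[i],
               db$channel[i], sprintf("duplicated spec (%s, %s, %s)",
                                      db$damage_class[i], db$ion[i],
                                      db$channel[i]))
  }
  if (completeness) {
    all_keys <- expand.grid(damage_class = DAMAGE_CLASSES,
                            ion = ION_SYMBOLS, channel = CHANNELS,
                            stringsAsFactors = FALSE)
    missing <- !(paste(all_keys$damage_class, all_keys$ion, all_keys$channel)
                 %in% key)
    for (i in which(missing)) {
      rep <- add(rep, "completeness", all_keys$damage_class[i],
                 all_keys$ion[i], all_keys$channel[i],
                 sprintf("missing spec (%s, %s, %s)",
                         all_keys$damage_class[i], all_keys$ion[i],
                         all_keys$channel[i]))
    }
  }

  for (i in seq_len(nrow(db))) {
    p <- unlist(db[i, c("p1", "p2", "p3", "p4", "p5")])
    if (is.na(p[1]) || p[1] <= 0) {
      rep <- add(rep, "positivity", db$damage_class[i], db$ion[i],
                 db$channel[i], sprintf("(%s, %s, %s): p1 must be > 0",
                                        db$damage_class[i], db$ion[i],
                                        db$channel[i]))
    }
    if (xor(is.na(p[2]), is.na(p[3]))) {
      rep <- add(rep, "term_pairing", db$damage_class[i], db$ion[i],
                 db$channel[i],
                 sprintf("(%s, %s, %s): p2 and p3 must be present or absent together",
                         db$damage_class[i], db$ion[i], db$channel[i]))
    }
    if (xor(is.na(p[4]), is.na(p[5]))) {
      rep <- add(rep, "term_pairing", db$damage_class[i], db$ion[i],
                 db$channel[i],
                 sprintf("(%s, %s, %s): p4 and p5 must be present or absent together",
                         db$damage_class[i], db$ion[i], db$channel[i]))
    }
    bad_pos <- which(!is.na(p[-1]) & p[-1] <= 0)
    for (j in bad_pos) {
      rep <- add(rep, "positivity", db$damage_class[i], db$ion[i],
                 db$channel[i],
                 sprintf("(%s, %s, %s): p%d must be > 0 when present",
                         db$damage_class[i], db$ion[i], db$channel[i], j + 1L))
    }
  }

  # universal low-LET yield: one p1 per (damage_class, channel)
  grp <- split(seq_len(nrow(db)), paste(db$damage_class, db$channel))
  for (g in grp) {
    p1s <- unique(db$p1[g])
    p1s <- p1s[!is.na(p1s)]
    if (length(p1s) > 1L) {
      rep <- add(rep, "universal_p1", db$damage_class[g[1]], "*",
                 db$channel[g[1]],
                 sprintf("(%s, %s): p1 not universal across ions (values: %s)",
                         db$damage_class[g[1]], db$channel[g[1]],
                         paste(p1s, collapse = ", ")))
    }
  }
  rownames(rep) <- NULL
  rep
}

#' Query one parameter set
#'
#' @param db A `"yield_param_db"` data.frame.
#' @param ion Ion symbol (H, He, Li, Be, B, C, N, O, Ne);
#'   case-insensitive.
#' @param damage_class One of SB, SSB, DSB, DSB_CLUSTER, DSB_SITE
#'   (case-insensitive, `-` accepted for `_`).
#' @param channel One of TOTAL, DIRECT, INDIRECT.
#' @return An object of class `"yield_params"`: a list with elements
#'   `ion`, `damage_class`, `channel`, `form` and the numeric vector `p`
#'   (`p1`..`p5`, `NA` marking omitted terms).
#' @export
query_params <- function(db, ion, damage_class, channel = "TOTAL") {
  ion <- as_ion(ion)
  damage_class <- as_damage_class(damage_class)
  channel <- as_channel(channel)
  i <- which(db$ion == ion & db$damage_class == damage_class &
               db$channel == channel)
  if (length(i) == 0L) {
    stop_validation(sprintf("no parameter set for (%s, %s, %s)",
                            damage_class, ion, channel))
  }
  row <- db[i[1], ]
  structure(
    list(ion = ion, damage_class = damage_class, channel = channel,
         form = row$form,
         p = c(p1 = row$p1, p2 = row$p2, p3 = row$p3,
               p4 = row$p4, p5 = row$p5)),
    class = "yield_params")
}

#' @export
print.yield_params <- function(x, ...) {
  cat(sprintf("<yield_params> %s %s (%s), form = %s\n",
              x$ion, x$damage_class, x$channel, x$form))
  p <- x$p
  cat("  ", paste(sprintf("%s = %s", names(p),
                          ifelse(is.na(p), "absent", format(p))),
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.yield_param_db <- function(x, ...) {
  cat(sprintf("<yield_param_db> %d parameter sets (%d ions, %d classes, %d channels)\n",
              nrow(x), length(unique(x$ion)),
              length(unique(x$damage_class)), length(unique(x$channel))))
  NextMethod()
}

# shortest decimal string that round-trips to the stored double
format_shortest <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- as.character(v)  # up to 15 significant digits, no padding
    if (identical(as.numeric(s), v)) return(s)
    sprintf("%.17g", v)
  }, character(1))
}

#' Save a parameter database
#'
#' Writes the collection in the documented CSV or JSON schema with a fixed
#' column order and shortest round-trip float formatting, so saving is
#' bit-stable and `load_params(save_params(db, f))` is the identity.
#' Absent terms are written as the token `NA` in CSV and as `null` in JSON.
#'
#' @param db A `"yield_param_db"` data.frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; default inferred from the file
#'   extension.
#' @return `path`, invisibly.
#' @export
save_params <- function(db, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("csv", "json")) {
      stop_validation("cannot infer format; use a .csv or .json path")
    }
  }
  cols <- c("damage_class", "ion", "channel", "p1", "p2", "p3", "p4", "p5")
  out <- db[order(match(db$damage_class, DAMAGE_CLASSES),
                  match(db$ion, ION_SYMBOLS),
                  match(db$channel, CHANNELS)), cols]
  ok <- tryCatch({
    if (format == "csv") {
      lines <- c(
        paste(cols, collapse = ","),
        vapply(seq_len(nrow(out)), function(i) {
          paste(c(out$damage_class[i], out$ion[i], out$channel[i],
                  format_shortest(unlist(out[i, 4:8]))), collapse = ",")
        }, character(1)))
      writeLines(lines, path)
    } else {
      recs <- lapply(seq_len(nrow(out)), function(i) {
        r <- list(damage_class = out$damage_class[i], ion = out$ion[i],
                  channel = out$channel[i])
        for (p in c("p1", "p2", "p3", "p4", "p5")) {
          v <- out[[p]][i]
          r[[p]] <- if (is.na(v)) NULL else v
        }
        r
      })
      writeLines(jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA,
                                  null = "null", pretty = TRUE), path)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_io(sprintf("cannot write %s: %s", path,
                                   conditionMessage(ok)))
  invisible(path)
}
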