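DATASET_COLUMNS <- c("catalyst_conc", "time_s", "temperature_C",
                     "sludge_conc", "protein_mg_L")

#' Applicable factor ranges for a catalyst
#'
#' The intervals over which the fitted model is declared valid:
#' temperature 90-140 degrees C, sludge 30-95 g/kg, time 0-18000 s, and
#' catalyst concentration 9-20 g/kg (sulfuric acid) or 0-4 g/kg (sodium
#' hydroxide).
#'
#' @param catalyst `"acid"` or `"alkali"`.
#' @return Named list of `c(lower, upper)` intervals, one per factor.
#' @export
applicable_ranges <- function(catalyst = c("acid", "alkali")) {
  catalyst <- match.arg(catalyst)
  list(
    catalyst_conc = if (catalyst == "acid") c(9, 20) else c(0, 4),
    time_s        = c(0, 18000),
    temperature_C = c(90, 140),
    sludge_conc   = c(30, 95)
  )
}

new_dataset <- function(data, catalyst, ranges = applicable_ranges(catalyst)) {
  stopifnot(is.data.frame(data), nrow(data) > 0,
            identical(names(data), DATASET_COLUMNS))
  # validates the condition columns
  reaction_conditions(data$catalyst_conc, data$time_s,
                      data$temperature_C, data$sludge_conc)
  if (any(!is.finite(data$protein_mg_L)) || any(data$protein_mg_L < 0))
    stop("dataset: protein_mg_L must be finite and >= 0", call. = FALSE)
  structure(list(catalyst = catalyst, data = data, ranges = ranges),
            class = "protein_dataset")
}

#' @export
print.protein_dataset <- function(x, ...) {
  cat(sprintf("Sludge protein dataset (%s catalysis): %d observations\n",
              x$catalyst, nrow(x$data)))
  print(utils::head(x$data, 6))
  if (nrow(x$data) > 6) cat("...\n")
  invisible(x)
}

#' Extract the condition rows of a dataset
#'
#' @param dataset a `protein_dataset`.
#' @return A [reaction_conditions()] data frame.
#' @export
dataset_conditions <- function(dataset) {
  reaction_conditions(dataset$data$catalyst_conc, dataset$data$time_s,
                      dataset$data$temperature_C, dataset$data$sludge_conc)
}

load_fixture <- function(file, catalyst) {
  path <- system.file("extdata", file, package = "sludgekin", mustWork = TRUE)
  read_protein_dataset(path, catalyst)
}

#' Published acid-thermal dataset
#'
#' The 20-run sulfuric-acid-catalysed hydrolysis experiment: catalyst
#' concentration, time, temperature, initial sludge concentration and the
#' measured supernatant protein concentration, in the published row order.
#'
#' @return A `protein_dataset` with 20 observations and the acid applicable
#'   ranges attached.
#' @export
load_acid_dataset <- function() load_fixture("acid_thermal.csv", "acid")

#' Published alkali-thermal dataset
#'
#' The 20-run sodium-hydroxide-catalysed counterpart of
#' [load_acid_dataset()].
#'
#' @return A `protein_dataset` with 20 observations and the alkali
#'   applicable ranges attached.
#' @export
load_alkali_dataset <- function() load_fixture("alkali_thermal.csv", "alkali")

#' Read a protein dataset from delimited text
#'
#' Expects a comma-separated file with header columns `catalyst_conc`,
#' `time_s`, `temperature_C`, `sludge_conc`, `protein_mg_L`. Lines starting
#' with `#` (provenance comments written by the synthetic generator) are
#' skipped.
#'
#' @param path file path.
#' @param catalyst `"acid"` or `"alkali"`; attaches the matching applicable
#'   ranges.
#' @return A `protein_dataset`.
#' @export
read_protein_dataset <- function(path, catalyst = c("acid", "alkali")) {
  catalyst <- match.arg(catalyst)
  if (!file.exists(path))
    stop("read_protein_dataset: file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    read.csv(path, comment.char = "#", colClasses = "character",
             check.names = FALSE),
    error = function(e) stop("read_protein_dataset: schema error: ",
                             conditionMessage(e), call. = FALSE))
  missing <- setdiff(DATASET_COLUMNS, names(raw))
  if (length(missing) > 0)
    stop("read_protein_dataset: schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(raw) == 0)
    stop("read_protein_dataset: schema error: no data rows", call. = FALSE)
  raw <- raw[DATASET_COLUMNS]
  num <- lapply(DATASET_COLUMNS, function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad) > 0)
      stop(sprintf("read_protein_dataset: parse error in column '%s', row %d",
                   col, bad[1]), call. = FALSE)
    v
  })
  names(num) <- DATASET_COLUMNS
  new_dataset(as.data.frame(num), catalyst)
}

#' Write a protein dataset as delimited text
#'
#' Values are written with `as.character()` precision, so a write/read
#' round trip reproduces every value exactly as decimal text. An optional
#' provenance string is prefixed as a `#` comment line.
#'
#' @param dataset a `protein_dataset`.
#' @param path output file path.
#' @param provenance optional character vector of comment lines (without the
#'   leading `#`).
#' @return `path`, invisibly.
#' @export
write_protein_dataset <- function(dataset, path, provenance = NULL) {
  stopifnot(inherits(dataset, "protein_dataset"))
  lines <- character(0)
  if (!is.null(provenance))
    lines <- paste0("# ", provenance)
  lines <- c(lines, paste(DATASET_COLUMNS, collapse = ","))
  body <- apply(dataset$data, 1L, function(r)
    paste(vapply(r, function(v) as.character(as.numeric(v)), character(1)),
          collapse = ","))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Check dataset rows against the applicable ranges
#'
#' Advisory validation: every cell outside its factor's applicable interval
#' yields one violation record. Nothing is dropped or altered — the published
#' acid table itself contains catalyst concentrations outside its stated
#' range, and the published fit used all rows.
#'
#' @param dataset a `protein_dataset`.
#' @param warn emit a warning summarising violations (default `TRUE`).
#' @return Data frame with columns `row`, `factor`, `value`, `lower`,
#'   `upper`; zero rows when fully in range.
#' @export
validate_ranges <- function(dataset, warn = TRUE) {
  stopifnot(inherits(dataset, "protein_dataset"))
  out <- list()
  for (f in names(dataset$ranges)) {
    r <- dataset$ranges[[f]]
    v <- dataset$data[[f]]
    bad <- which(v < r[1] | v > r[2])
    if (length(bad) > 0)
      out[[f]] <- data.frame(row = bad, factor = f, value = v[bad],
                             lower = r[1], upper = r[2])
  }
  res <- if (length(out) == 0) {
    data.frame(row = integer(0), factor = character(0), value = numeric(0),
               lower = numeric(0), upper = numeric(0))
  } else {
    do.call(rbind, unname(out))
  }
  if (warn && nrow(res) > 0)
    warning(sprintf("%d value(s) outside the applicable ranges (%s)",
                    nrow(res), paste(unique(res$factor), collapse = ", ")),
            call. = FALSE)
  res
}

#' Drop rows that violate the applicable ranges
#'
#' Sensitivity-analysis helper: returns the dataset restricted to rows whose
#' every factor lies inside the applicable intervals.
#'
#' @param dataset a `protein_dataset`.
#' @return A `protein_dataset` with the offending rows removed.
#' @export
filter_ranges <- function(dataset) {
  viol <- validate_ranges(dataset, warn = FALSE)
  if (nrow(viol) == 0) return(dataset)
  keep <- setdiff(seq_len(nrow(dataset$data)), unique(viol$row))
  if (length(keep) == 0)
    stop("filter_ranges: no rows remain in range", call. = FALSE)
  new_dataset(dataset$data[keep, , drop = FALSE], dataset$catalyst,
              dataset$ranges)
}
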