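#' @importFrom tibble tibble as_tibble
NULL

# canonical column schema (long form; catch counts one row per age)
MORT_COLUMNS <- c("dataset_id", "study_id", "species", "subfamily", "type",
                  "age", "t1", "t2", "cohort", "count",
                  "estimate", "se", "ci_lo", "ci_hi", "ci_level", "n", "h_rough")
MORT_TYPES <- c("age", "range", "catch")
LEVEL_NAMES <- c("subfamily", "species", "study", "dataset")

load_error <- function(rows, msg) {
  stop(sprintf("mortality data: %s (row%s %s)", msg,
               if (length(rows) > 1) "s" else "",
               paste(rows, collapse = ", ")), call. = FALSE)
}

#' Assemble a mortality-data collection from a data frame
#'
#' Validates a data frame in the canonical long-form schema and builds a
#' \code{mort_data} object: per-row records (with logit-scale precisions
#' resolved for survival estimates), a per-dataset taxonomy/harvest table,
#' and the catch-at-age count vectors grouped by cohort.
#'
#' The schema has one row per age-specific estimate (\code{type = "age"}),
#' one row per age-range estimate (\code{type = "range"}; \code{t2 = NA}
#' means open-ended, closed at \code{config$max_age}), and one row per
#' (cohort, age) catch count (\code{type = "catch"}). Every row carries the
#' dataset's taxonomy labels (\code{dataset_id, study_id, species,
#' subfamily}) and its rough harvest rate \code{h_rough}; these must be
#' constant within a dataset, nested (each dataset in exactly one study,
#' each study in one species, each species in one subfamily), and
#' \code{h_rough} must lie in (0, 0.5] so that the Uniform(0, 2 h_rough)
#' harvest prior is a valid rate (use a tiny value such as 0.001 for
#' unharvested populations). Validation failures report row numbers.
#'
#' @param df Data frame in the canonical schema (see
#'   \code{\link{read_mortality_data}}); missing optional columns are added
#'   as \code{NA}.
#' @param config A \code{\link{natmort_config}} list (controls the
#'   no-information precision default and \code{max_age}).
#' @return An object of class \code{mort_data} with elements
#'   \code{survival} (tibble of age/range records with resolved \code{tau}),
#'   \code{catch} (tibble of per-cohort count vectors), and \code{datasets}
#'   (tibble of taxonomy labels and \code{h_rough} per dataset).
#' @export
as_mort_data <- function(df, config = natmort_config()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_required <- setdiff(c("dataset_id", "study_id", "species", "subfamily",
                                "type", "h_rough"), names(df))
  if (length(missing_required))
    stop("mortality data: missing required column(s): ",
         paste(missing_required, collapse = ", "), call. = FALSE)
  for (col in setdiff(MORT_COLUMNS, names(df))) df[[col]] <- NA
  df <- df[MORT_COLUMNS]
  df$row <- seq_len(nrow(df))
  if (nrow(df) == 0L) stop("mortality data: no rows", call. = FALSE)

  bad <- df$row[!(df$type %in% MORT_TYPES)]
  if (length(bad)) load_error(bad, "'type' must be one of age, range, catch")
  for (col in c("dataset_id", "study_id", "species", "subfamily")) {
    bad <- df$row[is.na(df[[col]]) | df[[col]] == ""]
    if (length(bad)) load_error(bad, paste0("missing '", col, "' label"))
  }

  # taxonomy: one label per level per dataset, strict nesting up the tree
  tax <- unique(df[c("dataset_id", "study_id", "species", "subfamily", "h_rough")])
  if (anyDuplicated(tax$dataset_id)) {
    dup <- tax$dataset_id[duplicated(tax$dataset_id)]
    stop("mortality data: dataset(s) with inconsistent taxonomy or h_rough labels: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  for (pair in list(c("study_id", "species"), c("species", "subfamily"))) {
    u <- unique(tax[pair])
    if (anyDuplicated(u[[1]]))
      stop(sprintf("mortality data: non-nested taxonomy: %s '%s' mapped to several %s labels",
                   pair[1], u[[1]][duplicated(u[[1]])][1], pair[2]), call. = FALSE)
  }
  bad <- df$row[is.na(df$h_rough) | df$h_rough <= 0 | df$h_rough > 0.5]
  if (length(bad))
    load_error(bad, paste("'h_rough' must lie in (0, 0.5] so that Uniform(0, 2*h_rough)",
                          "is a valid harvest-rate prior; rescale or use e.g. 0.001",
                          "for unharvested populations"))

  est_rows <- df$type %in% c("age", "range")
  bad <- df$row[est_rows & (is.na(df$estimate) | df$estimate < 0 | df$estimate > 1)]
  if (length(bad)) load_error(bad, "survival 'estimate' must lie in [0, 1]")
  at_bound <- est_rows & (df$estimate <= 0 | df$estimate >= 1)
  if (any(at_bound, na.rm = TRUE)) {
    warning(sprintf("truncated %d boundary survival estimate(s) into [1e-6, 1 - 1e-6] (rows %s)",
                    sum(at_bound), paste(df$row[at_bound], collapse = ", ")), call. = FALSE)
    df$estimate[at_bound] <- pmin(pmax(df$estimate[at_bound], 1e-6), 1 - 1e-6)
  }

  bad <- df$row[df$type == "age" & (is.na(df$age) | df$age < 0 | df$age != floor(df$age))]
  if (length(bad)) load_error(bad, "age-specific rows need a non-negative integer 'age'")
  rng <- df$type == "range"
  bad <- df$row[rng & (is.na(df$t1) | df$t1 < 0 | df$t1 != floor(df$t1))]
  if (length(bad)) load_error(bad, "range rows need a non-negative integer 't1'")
  df$t2[rng & is.na(df$t2)] <- config$max_age  # open-ended ranges ("5+")
  bad <- df$row[rng & df$t1 > df$t2]
  if (length(bad)) load_error(bad, "range rows need t1 <= t2")
  ctc <- df$type == "catch"
  bad <- df$row[ctc & (is.na(df$age) | is.na(df$cohort) | is.na(df$count) |
                         df$count < 0 | df$count != floor(df$count))]
  if (length(bad)) load_error(bad, "catch rows need 'age', 'cohort' and a non-negative integer 'count'")

  sv <- df[est_rows, ]
  tau <- vapply(seq_len(nrow(sv)), function(i)
    precision_from_fallbacks(sv$estimate[i], se = sv$se[i],
                             ci_lo = sv$ci_lo[i], ci_hi = sv$ci_hi[i],
                             ci_level = ifelse(is.na(sv$ci_level[i]), 0.95, sv$ci_level[i]),
                             n = sv$n[i],
                             default_logit_sd = config$default_logit_sd),
    numeric(1))
  survival <- tibble(
    dataset_id = sv$dataset_id, type = sv$type,
    age = ifelse(sv$type == "age", sv$age, NA_real_),
    t1 = ifelse(sv$type == "range", sv$t1, NA_real_),
    t2 = ifelse(sv$type == "range", sv$t2, NA_real_),
    estimate = sv$estimate, tau = tau)

  cc <- df[ctc, ]
  catch <- if (nrow(cc)) {
    key <- paste(cc$dataset_id, cc$cohort, sep = "\r")
    grp <- split(cc, key)
    tibble(
      dataset_id = unname(vapply(grp, function(g) g$dataset_id[1], character(1))),
      cohort = unname(vapply(grp, function(g) as.character(g$cohort[1]), character(1))),
      first_age = unname(vapply(grp, function(g) min(g$age), numeric(1))),
      counts = unname(lapply(grp, function(g) {
        g <- g[order(g$age), ]
        if (any(diff(g$age) != 1))
          load_error(g$row, "catch ages within a cohort must be consecutive")
        if (sum(g$count) <= 0) load_error(g$row, "catch cohort has zero total count")
        as.integer(g$count)
      })))
  } else {
    tibble(dataset_id = character(0), cohort = character(0),
           first_age = numeric(0), counts = list())
  }

  datasets <- tibble(dataset_id = tax$dataset_id, study_id = tax$study_id,
                     species = tax$species, subfamily = tax$subfamily,
                     h_rough = tax$h_rough)
  datasets <- datasets[order(datasets$dataset_id), ]
  structure(list(survival = survival, catch = catch, datasets = datasets,
                 config = config),
            class = "mort_data")
}

#' Read a mortality-data collection from a CSV file
#'
#' Reads a delimited text file in the canonical long-form schema (see
#' \code{\link{as_mort_data}} for the column contract and validation rules)
#' and returns a validated \code{mort_data} collection. Errors carry data
#' row numbers (header excluded).
#'
#' @param path Path to a CSV file.
#' @inheritParams as_mort_data
#' @export
read_mortality_data <- function(path, config = natmort_config()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_mort_data(df, config = config)
}

#' Write a mortality-data collection to CSV
#'
#' Serialises a \code{mort_data} collection back to the canonical long-form
#' schema, so that \code{read_mortality_data(write_mortality_data(x, f))}
#' round-trips.
#'
#' @param x A \code{mort_data} object.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_mortality_data <- function(x, path) {
  stopifnot(inherits(x, "mort_data"))
  ds <- x$datasets
  meta <- function(id) ds[match(id, ds$dataset_id), ]
  sv <- x$survival
  rows <- tibble(
    dataset_id = sv$dataset_id, study_id = meta(sv$dataset_id)$study_id,
    species = meta(sv$dataset_id)$species, subfamily = meta(sv$dataset_id)$subfamily,
    type = sv$type, age = sv$age, t1 = sv$t1, t2 = sv$t2,
    cohort = NA_character_, count = NA_real_, estimate = sv$estimate,
    se = sv$estimate * (1 - sv$estimate) / sqrt(sv$tau),  # encodes tau exactly
    ci_lo = NA_real_, ci_hi = NA_real_, ci_level = NA_real_, n = NA_real_,
    h_rough = meta(sv$dataset_id)$h_rough)
  if (nrow(x$catch)) {
    ct <- x$catch
    crows <- do.call(rbind, lapply(seq_len(nrow(ct)), function(i) {
      ages <- ct$first_age[i] + seq_along(ct$counts[[i]]) - 1
      m <- meta(ct$dataset_id[i])
      tibble(dataset_id = ct$dataset_id[i], study_id = m$study_id,
             species = m$species, subfamily = m$subfamily, type = "catch",
             age = ages, t1 = NA_real_, t2 = NA_real_, cohort = ct$cohort[i],
             count = as.numeric(ct$counts[[i]]), estimate = NA_real_,
             se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
             ci_level = NA_real_, n = NA_real_, h_rough = m$h_rough)
    }))
    rows <- rbind(rows, crows)
  }
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.mort_data <- function(x, ...) {
  cat(sprintf("Mortality data collection: %d datasets, %d studies, %d species, %d subfamilies\n",
              nrow(x$datasets), length(unique(x$datasets$study_id)),
              length(unique(x$datasets$species)), length(unique(x$datasets$subfamily))))
  cat(sprintf("  %d age-specific estimates, %d age-range estimates, %d catch cohorts\n",
              sum(x$survival$type == "age"), sum(x$survival$type == "range"),
              nrow(x$catch)))
  invisible(x)
}

#' Load a local copy of the published phocid-seal data deposit
#'
#' Maps a locally downloaded data deposit into the canonical schema. Files
#' already in the canonical schema (one or more \code{*.csv} in the
#' directory, or a single CSV path) are loaded directly and concatenated.
#' The loader never accesses the network; the deposit must be downloaded by
#' the user beforehand.
#'
#' @param path Directory containing canonical-schema CSV file(s), or a
#'   single CSV file.
#' @inheritParams as_mort_data
#' @export
read_dryad_layout <- function(path, config = natmort_config()) {
  if (file.exists(path) && !dir.exists(path))
    return(read_mortality_data(path, config = config))
  if (!dir.exists(path))
    stop("deposit path not found: ", path,
         "\nExpected a directory of canonical-schema CSV files ",
         "(columns: ", paste(MORT_COLUMNS, collapse = ", "), ") or a single CSV.",
         call. = FALSE)
  files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files))
    stop("no CSV files found under ", path,
         "\nExpected canonical-schema CSV files (columns: ",
         paste(MORT_COLUMNS, collapse = ", "), ").", call. = FALSE)
  dfs <- lapply(files, utils::read.csv, stringsAsFactors = FALSE)
  for (d in dfs) {
    miss <- setdiff(c("dataset_id", "study_id", "species", "subfamily", "type"), names(d))
    if (length(miss))
      stop("unrecognized deposit layout: file missing column(s) ",
           paste(miss, collapse = ", "), "; expected the canonical schema.",
           call. = FALSE)
  }
  all_cols <- Reduce(union, lapply(dfs, names))
  dfs <- lapply(dfs, function(d) { for (cl in setdiff(all_cols, names(d))) d[[cl]] <- NA; d[all_cols] })
  as_mort_data(do.call(rbind, dfs), config = config)
}
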