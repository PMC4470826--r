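# Cohort file import/export, unit conversion, validation and Table-style
# descriptive statistics.

# canonical column -> accepted header spellings (case/punctuation-insensitive)
default_column_candidates <- function() {
  list(
    id = c("id", "subject_id", "participant_id", "pid"),
    age = c("age", "age_years", "age_yrs"),
    sex = c("sex", "gender"),
    weight = c("weight", "weight_kg", "mass", "mass_kg", "body_weight"),
    height = c("height", "height_m", "height_cm", "body_height"),
    hiv_status = c("hiv_status", "hiv", "hivstatus", "hiv_result"),
    scr = c("scr", "creatinine", "serum_creatinine", "s_creatinine", "crea"),
    scysc = c("scysc", "cystatin_c", "cystatin", "serum_cystatin_c", "cysc")
  )
}

norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

normalize_hiv <- function(x) {
  s <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(s))
  out[s %in% c("positive", "pos", "+", "1", "true", "yes", "hiv+")] <- "positive"
  out[s %in% c("negative", "neg", "-", "0", "false", "no", "hiv-")] <- "negative"
  out[is.na(s) | s == ""] <- "unknown"
  out
}

#' Read a cohort table from CSV or XLS/XLSX
#'
#' Maps file headers onto the canonical schema (`id`, `age`, `sex`, `weight`,
#' `height`, `hiv_status`, `scr`, `scysc`), converts declared source units,
#' validates each row, and logs exclusions. Extra columns are carried through
#' untouched. Spreadsheet input needs the readxl package.
#'
#' Unit conversions (applied only when declared, never guessed):
#' creatinine micromol/L -> mg/dL by dividing by 88.4; cystatin C nmol/L ->
#' mg/L by dividing by 74.9. Heights > 3 are taken to be centimetres and
#' divided by 100.
#'
#' Rows are excluded (with a reason in the exclusion log) when `scr`, `scysc`,
#' `age` or `sex` is missing/unparseable, when a biomarker is non-positive, or
#' when `age < 18` (adult cohorts only).
#'
#' @param path CSV, XLS or XLSX file.
#' @param col_map optional named character vector mapping canonical names to
#'   file headers, e.g. `c(scr = "crea_umol")`; unmapped canonical columns are
#'   matched against common spellings.
#' @param units named list of source units: `scr` one of `"mg/dL"`
#'   (default) or `"umol/L"`; `scysc` one of `"mg/L"` (default) or `"nmol/L"`.
#' @return a tibble of class `egfr_cohort` with attributes `provenance`
#'   (file, format, units) and `exclusions` (tibble: `row`, `id`, `reason`).
#' @export
read_cohort <- function(path, col_map = NULL,
                        units = list(scr = "mg/dL", scysc = "mg/L")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xls", "xlsx")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading ", ext, " files requires the readxl package", call. = FALSE)
    }
    readxl::read_excel(path)
  } else {
    # read everything as character and convert with base R's correctly
    # rounded parser, so written doubles round-trip bit-exactly
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = "c"))
    nonnum <- c("id", "sex", "hiv_status")
    for (col in setdiff(names(raw), nonnum)) {
      raw[[col]] <- utils::type.convert(raw[[col]], as.is = TRUE)
    }
    raw
  }
  as_cohort(raw, col_map = col_map, units = units,
            provenance = list(file = path, format = ext))
}

#' Coerce a data frame to a validated cohort
#'
#' The in-memory counterpart of [read_cohort()]; applies the same column
#' mapping, unit conversion, validation and exclusion logging.
#'
#' @param data a data frame.
#' @inheritParams read_cohort
#' @param provenance optional list recorded on the result.
#' @return a tibble of class `egfr_cohort`; see [read_cohort()].
#' @export
as_cohort <- function(data, col_map = NULL,
                      units = list(scr = "mg/dL", scysc = "mg/L"),
                      provenance = list(file = NA_character_,
                                        format = "data.frame")) {
  cand <- default_column_candidates()
  hdr <- norm_header(names(data))
  mapped <- character(0)
  for (canon in names(cand)) {
    src <- NULL
    if (!is.null(col_map) && canon %in% names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(data)) {
        stop("col_map names '", src, "' for '", canon,
             "' but the file has no such column; available: ",
             paste(names(data), collapse = ", "), call. = FALSE)
      }
    } else {
      hit <- which(hdr %in% norm_header(cand[[canon]]))
      if (length(hit) > 0) src <- names(data)[hit[1]]
    }
    if (!is.null(src) && src != canon) {
      names(data)[names(data) == src] <- canon
    }
    if (canon %in% names(data)) mapped <- c(mapped, canon)
  }
  required <- c("age", "sex", "scr", "scysc")
  miss <- setdiff(required, mapped)
  if (length(miss) > 0) {
    stop("could not locate required column(s) ", paste(miss, collapse = ", "),
         "; file columns are: ", paste(names(data), collapse = ", "),
         "; use col_map to map them", call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (!"id" %in% names(data)) data$id <- as.character(seq_len(nrow(data)))
  data$id <- as.character(data$id)
  if (anyDuplicated(data$id)) {
    stop("duplicate subject id(s): ",
         paste(unique(data$id[duplicated(data$id)]), collapse = ", "),
         call. = FALSE)
  }

  num <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    suppressWarnings(as.numeric(as.character(x)))
  }
  data$age <- num(data$age)
  data$scr <- num(data$scr)
  data$scysc <- num(data$scysc)
  if ("weight" %in% names(data)) data$weight <- num(data$weight)
  if ("height" %in% names(data)) {
    data$height <- num(data$height)
    cm <- !is.na(data$height) & data$height > 3
    data$height[cm] <- data$height[cm] / 100
  }

  scr_unit <- units$scr %||% "mg/dL"
  if (scr_unit %in% c("umol/L", "µmol/L", "micromol/L")) {
    data$scr <- data$scr / 88.4
  } else if (scr_unit != "mg/dL") {
    stop("unsupported creatinine unit '", scr_unit, "'", call. = FALSE)
  }
  scysc_unit <- units$scysc %||% "mg/L"
  if (scysc_unit == "nmol/L") {
    data$scysc <- data$scysc / 74.9
  } else if (scysc_unit != "mg/L") {
    stop("unsupported cystatin C unit '", scysc_unit, "'", call. = FALSE)
  }

  sex_norm <- tryCatch(normalize_sex(data$sex), error = function(e) e)
  if (inherits(sex_norm, "error")) {
    # re-parse per row so the bad rows are excluded rather than fatal
    sex_norm <- vapply(as.character(data$sex), function(s) {
      tryCatch(normalize_sex(s), error = function(e) NA_character_)
    }, character(1), USE.NAMES = FALSE)
  }
  data$sex <- sex_norm
  data$hiv_status <- if ("hiv_status" %in% names(data)) {
    normalize_hiv(data$hiv_status)
  } else "unknown"

  reason <- rep(NA_character_, nrow(data))
  flag <- function(cond, why) reason[is.na(reason) & cond] <<- why
  flag(is.na(data$scr), "missing or unparseable serum creatinine")
  flag(is.na(data$scysc), "missing or unparseable serum cystatin C")
  flag(is.na(data$age), "missing or unparseable age")
  flag(is.na(data$sex), "missing or unrecognised sex")
  flag(!is.na(data$scr) & data$scr <= 0, "non-positive serum creatinine")
  flag(!is.na(data$scysc) & data$scysc <= 0, "non-positive serum cystatin C")
  flag(!is.na(data$age) & data$age < 18, "age below 18")

  drop <- !is.na(reason)
  exclusions <- tibble::tibble(row = which(drop), id = data$id[drop],
                               reason = reason[drop])
  kept <- data[!drop, , drop = FALSE]
  structure(kept,
            provenance = c(provenance,
                           list(units = list(scr = scr_unit,
                                             scysc = scysc_unit),
                                n_read = nrow(data),
                                n_kept = nrow(kept))),
            exclusions = exclusions,
            class = unique(c("egfr_cohort", class(kept))))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Exclusion log of a cohort
#'
#' @param cohort an `egfr_cohort`.
#' @return tibble: `row`, `id`, `reason` (empty when nothing was dropped).
#' @export
cohort_exclusions <- function(cohort) {
  attr(cohort, "exclusions") %||%
    tibble::tibble(row = integer(), id = character(), reason = character())
}

#' Write a cohort to CSV
#'
#' Numeric columns are written at full precision, so
#' `read_cohort(write_cohort(x))` round-trips values bit-exactly.
#'
#' @param cohort an `egfr_cohort` (or plain data frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      # 17 significant digits uniquely identify any double
      out[[col]] <- sprintf("%.17g", out[[col]])
    }
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Descriptive statistics by HIV stratum
#'
#' Continuous variables are summarised as median and IQR (quantile type
#' `qtype`, default 7 = linear interpolation between order statistics) overall
#' and per HIV stratum, compared by t-test; categorical variables as counts
#' and percentages, compared by chi-square test.
#'
#' @param cohort an `egfr_cohort`.
#' @param continuous continuous columns to summarise (missing ones skipped;
#'   `bmi` is derived from weight/height when absent but derivable).
#' @param categorical categorical columns.
#' @param qtype quantile algorithm type passed to [stats::quantile()].
#' @param welch use Welch's t-test (default) rather than pooled variance.
#' @param yates apply Yates' continuity correction in 2x2 chi-square tests
#'   (default FALSE).
#' @return tibble, one row per variable x stratum (strata: `overall`,
#'   `positive`, `negative`), with `median`/`q1`/`q3` for continuous rows,
#'   `level`/`count`/`pct` for categorical rows, and `test`/`p_value`
#'   (repeated across the variable's rows).
#' @export
cohort_descriptives <- function(cohort,
                                continuous = c("age", "bmi", "scr", "scysc"),
                                categorical = "sex",
                                qtype = 7, welch = TRUE, yates = FALSE) {
  cohort <- tibble::as_tibble(cohort)
  if ("bmi" %in% continuous && !"bmi" %in% names(cohort) &&
      all(c("weight", "height") %in% names(cohort))) {
    cohort$bmi <- cohort$weight / cohort$height^2
  }
  hiv <- if ("hiv_status" %in% names(cohort)) cohort$hiv_status else
    rep("unknown", nrow(cohort))
  strata <- list(overall = rep(TRUE, nrow(cohort)),
                 positive = hiv == "positive",
                 negative = hiv == "negative")
  two_groups <- sum(strata$positive) >= 2 && sum(strata$negative) >= 2

  rows <- list()
  for (v in intersect(continuous, names(cohort))) {
    x <- cohort[[v]]
    p <- NA_real_
    if (two_groups) {
      p <- tryCatch(
        t.test(x[strata$positive], x[strata$negative],
               var.equal = !welch)$p.value,
        error = function(e) {
          warning("t-test failed for '", v, "' (", conditionMessage(e),
                  "); p set to NA", call. = FALSE)
          NA_real_
        })
    } else {
      warning("HIV stratum with < 2 subjects; t-test skipped for '", v, "'",
              call. = FALSE)
    }
    for (snm in names(strata)) {
      xs <- x[strata[[snm]] & !is.na(x)]
      q <- quantile(xs, c(0.25, 0.5, 0.75), type = qtype, names = FALSE)
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, type = "continuous", stratum = snm, level = NA_character_,
        n = length(xs), median = q[2], q1 = q[1], q3 = q[3],
        count = NA_integer_, pct = NA_real_, test = "t-test", p_value = p)
    }
  }
  for (v in intersect(categorical, names(cohort))) {
    x <- as.character(cohort[[v]])
    p <- NA_real_
    if (two_groups) {
      tab <- table(x, hiv == "positive")
      if (nrow(tab) >= 2) {
        p <- suppressWarnings(chisq.test(tab, correct = yates)$p.value)
      }
    } else {
      warning("HIV stratum with < 2 subjects; chi-square skipped for '", v,
              "'", call. = FALSE)
    }
    for (snm in names(strata)) {
      xs <- x[strata[[snm]]]
      for (lev in sort(unique(x))) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          variable = v, type = "categorical", stratum = snm, level = lev,
          n = length(xs), median = NA_real_, q1 = NA_real_, q3 = NA_real_,
          count = sum(xs == lev), pct = 100 * mean(xs == lev),
          test = "chi-square", p_value = p)
      }
    }
  }
  dplyr::bind_rows(rows)
}
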