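#' The ten harmonized PHI categories
#'
#' The admissible Protected Health Information categories used throughout the
#' package: `DATE`, `NAME`, `AGE`, `ID`, `PHONE`, `WEB`, `INSTITUTE`,
#' `STREET`, `CITY`, `ZIP`. Any other label must be harmonized (see
#' [harmonize_category()]) before entering a corpus.
#'
#' @return A character vector of length 10.
#' @export
#' @examples
#' phi_categories()
phi_categories <- function() {
  c("DATE", "NAME", "AGE", "ID", "PHONE", "WEB", "INSTITUTE",
    "STREET", "CITY", "ZIP")
}

# source-label -> harmonized-label map over the i2b2-style guideline labels.
# Labels mapped to "DROP" are excluded from harmonized corpora.
.harmonize_map <- local({
  m <- c(
    DATE = "DATE", NAME = "NAME", PATIENT = "NAME", DOCTOR = "NAME",
    USERNAME = "NAME", AGE = "AGE", ID = "ID", MEDICALRECORD = "ID",
    IDNUM = "ID", DEVICE = "ID", BIOID = "ID", HEALTHPLAN = "ID",
    LICENSE = "ID", ACCOUNT = "ID", SSN = "ID", VEHICLE = "ID",
    PHONE = "PHONE", FAX = "PHONE",
    WEB = "WEB", EMAIL = "WEB", URL = "WEB", IPADDRESS = "WEB",
    IPADDR = "WEB",
    INSTITUTE = "INSTITUTE", HOSPITAL = "INSTITUTE",
    ORGANIZATION = "INSTITUTE",
    STREET = "STREET", CITY = "CITY", ZIP = "ZIP",
    LOCATION = "STREET", `LOCATION-OTHER` = "STREET",
    PROFESSION = "DROP",
    `DAY-OF-WEEK` = "DROP", DAYOFWEEK = "DROP", SEASON = "DROP",
    HOLIDAY = "DROP", STATE = "DROP", COUNTRY = "DROP",
    DROP = "DROP"
  )
  m
})

#' Harmonize source PHI labels to the ten-category scheme
#'
#' Maps annotation-guideline labels onto the ten harmonized categories used
#' here: phone and fax merge into `PHONE`; email, URL and IP address merge
#' into `WEB`; organization and hospital merge into `INSTITUTE`; days of the
#' week, seasons, holidays, state and country are excluded (mapped to
#' `"DROP"`). Labels already in the harmonized set map to themselves, so the
#' mapping is idempotent. Extra site-specific labels can be supplied through
#' `extra`.
#'
#' @param labels Character vector of source labels (case-insensitive;
#'   internal spaces/underscores are treated as hyphens).
#' @param extra Optional named character vector of additional mappings,
#'   names = source labels, values = harmonized category or `"DROP"`.
#' @return Character vector of harmonized categories, with `"DROP"` marking
#'   excluded labels.
#' @export
#' @examples
#' harmonize_category(c("FAX", "EMAIL", "HOSPITAL", "SEASON", "DATE"))
harmonize_category <- function(labels, extra = NULL) {
  stopifnot(is.character(labels))
  key <- gsub("[ _]", "-", toupper(trimws(labels)))
  map <- .harmonize_map
  if (!is.null(extra)) {
    stopifnot(is.character(extra), !is.null(names(extra)))
    bad <- setdiff(unname(extra), c(phi_categories(), "DROP"))
    if (length(bad) > 0)
      abort(paste0("extra mappings must target the harmonized categories or DROP; ",
                   "offending value(s): ", paste(bad, collapse = ", ")))
    map[gsub("[ _]", "-", toupper(names(extra)))] <- unname(extra)
  }
  out <- unname(map[key])
  if (anyNA(out)) {
    unknown <- unique(labels[is.na(out)])
    abort(paste0(
      "unknown source label(s): ", paste(unknown, collapse = ", "),
      "\nadmissible labels: ", paste(sort(names(map)), collapse = ", ")))
  }
  out
}

#' PHI category counts of the reference corpora splits
#'
#' The per-category annotation counts of the two de-identification corpora
#' (a shared-task corpus split into training/validation, and a single-site
#' clinical corpus split into training/validation/test) that calibrate the
#' synthetic generator's default category weights.
#'
#' @return A tibble with columns `category`, `i2b2_training`,
#'   `i2b2_validation`, `uf_training`, `uf_validation`, `uf_test`.
#' @export
phi_category_counts <- function() {
  path <- system.file("extdata", "phi_category_counts.tsv", package = "deidtag")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_tibble(tab)
}

#' Published benchmark operating points
#'
#' Precision/recall/F1 operating points reported for BiLSTM-CRF
#' de-identification models (by word embedding, by training regime, and by
#' PHI category for the fine-tuned model), in strict and relaxed matching
#' modes. Used to validate the package's metric arithmetic.
#'
#' @return A tibble with columns `group`, `label`, `mode`, `precision`,
#'   `recall`, `f1`.
#' @export
benchmark_operating_points <- function() {
  path <- system.file("extdata", "benchmark_operating_points.tsv",
                      package = "deidtag")
  as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}
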