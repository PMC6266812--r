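# Internal constructor: every symptom column is 0/1/NA and carries a domain
# tag; subject_id, sex, age, ige_positive are recognized metadata.
new_phenotype_table <- function(df, domains) {
  stopifnot(is.data.frame(df), "subject_id" %in% names(df))
  meta <- intersect(c("subject_id", "sex", "age", "ige_positive"), names(df))
  symptoms <- setdiff(names(df), meta)
  untagged <- setdiff(symptoms, names(domains))
  if (length(untagged)) {
    stop("symptom column(s) without a domain tag: ",
         paste(untagged, collapse = ", "), call. = FALSE)
  }
  for (s in symptoms) {
    v <- df[[s]]
    if (!all(is.na(v) | v %in% c(0L, 1L))) {
      stop(sprintf("symptom column '%s' must be binary 0/1/missing", s),
           call. = FALSE)
    }
    df[[s]] <- as.integer(v)
  }
  structure(df, class = c("phenotype_table", "data.frame"),
            domains = domains[symptoms], symptoms = symptoms)
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d subjects, %d symptoms in %d domains\n",
              nrow(x), length(attr(x, "symptoms")),
              length(unique(attr(x, "domains")))))
  NextMethod()
}

#' Read a binary phenotype/questionnaire CSV
#'
#' Subjects are identified by a `subject_id` column (else the first column).
#' Symptom columns accept yes/no, y/n, true/false or 1/0 encodings (case
#' insensitive; empty and NA are missing) and are recoded to canonical 0/1;
#' any other value is a hard error naming the offending entries. Each symptom
#' column must carry a domain tag through `domains`.
#'
#' @param path CSV path.
#' @param domains named character vector mapping symptom columns to their
#'   allergic-disorder domain; defaults to [default_symptom_domains()].
#' @return a `phenotype_table`.
#' @export
read_phenotypes <- function(path, domains = default_symptom_domains()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(df)) names(df)[1] <- "subject_id"
  df$subject_id <- as.character(df$subject_id)
  meta <- intersect(c("subject_id", "sex", "age", "ige_positive"), names(df))
  symptoms <- setdiff(names(df), meta)
  recode <- function(v, col) {
    chr <- tolower(trimws(as.character(v)))
    out <- rep(NA_integer_, length(chr))
    out[chr %in% c("1", "yes", "y", "true")] <- 1L
    out[chr %in% c("0", "no", "n", "false")] <- 0L
    bad <- !(is.na(v) | chr == "" | chr == "na") & is.na(out)
    if (any(bad)) {
      stop(sprintf("unrecognized encoding in column '%s': %s", col,
                   paste(unique(chr[bad]), collapse = ", ")), call. = FALSE)
    }
    out
  }
  for (s in symptoms) df[[s]] <- recode(df[[s]], s)
  if ("ige_positive" %in% names(df)) {
    df$ige_positive <- recode(df$ige_positive, "ige_positive")
  }
  new_phenotype_table(df, domains = domains)
}

#' Write a phenotype table as CSV
#'
#' @param phenotypes a `phenotype_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  stopifnot(inherits(phenotypes, "phenotype_table"))
  utils::write.csv(as.data.frame(phenotypes), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Write and re-read an association results table
#'
#' The TSV layout mirrors the study's odds-ratio grid: one row per
#' (trait, threshold) cell with n_snps, delta, OR per SD, 95% CI bounds and
#' P-values. Numeric columns are written at full double precision so a
#' write-then-read round-trip is exact.
#'
#' @param results a data.frame of `association_result` rows (see
#'   [associate_case_control()]).
#' @param path output path.
#' @return `write_association_table()`: the path, invisibly;
#'   `read_association_table()`: the data.frame.
#' @export
write_association_table <- function(results, path) {
  stopifnot(is.data.frame(results))
  write_tsv_full(as.data.frame(results), path)
}

#' @rdname write_association_table
#' @export
read_association_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
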