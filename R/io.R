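#' @importFrom jsonlite toJSON write_json read_json
NULL

standardColumns <- c("subject_id", "age", "sex", "label", "stage")

#' Write a cohort to CSV
#'
#' Serializes a raw-scale \linkS4class{MarkerCohort} as a subject-level
#' CSV with header \code{subject_id, <marker names...>, age, sex, label,
#' stage}; a missing stage (controls) is an empty field. Numeric values
#' are written with full precision, so [readCohort()] round-trips the
#' cohort exactly.
#'
#' @param cohort A \linkS4class{MarkerCohort} on the raw concentration
#'   scale.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(is(cohort, "MarkerCohort"))
  if (isLogTransformed(cohort)) {
    stop("write the raw-scale cohort; this one is log-transformed")
  }
  conc <- t(assay(cohort))
  df <- data.frame(subject_id = colnames(cohort), check.names = FALSE)
  for (m in rownames(cohort)) df[[m]] <- sprintf("%.17g", conc[, m])
  cd <- colData(cohort)
  df$age <- sprintf("%.17g", cd$age)
  df$sex <- cd$sex
  df$label <- cd$label
  df$stage <- ifelse(is.na(cd$stage), "", as.character(cd$stage))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Reads a subject-level cohort table written by [writeCohort()] (or
#' assembled externally with the same schema) and validates it: unique
#' subject ids, strictly positive marker concentrations, stage present
#' for every case and absent for every control. Errors name the
#' offending subject and column.
#'
#' @param path CSV file with header \code{subject_id, <markers...>, age,
#'   sex, label, stage}.
#' @return A \linkS4class{MarkerCohort}.
#' @export
readCohort <- function(path) {
  df <- tryCatch(
    read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
             colClasses = "character"),
    error = function(e) stop("cannot read cohort CSV '", path,
                             "': ", conditionMessage(e)))
  miss <- setdiff(standardColumns, names(df))
  if (length(miss) || nrow(df) == 0L) {
    stop("cohort CSV '", path, "' does not match the schema ",
         "(subject_id, <markers...>, age, sex, label, stage)",
         if (length(miss)) paste0("; missing: ",
                                  paste(miss, collapse = ", ")))
  }
  markers <- setdiff(names(df), standardColumns)
  if (!length(markers)) stop("cohort CSV has no marker columns")
  if (anyDuplicated(df$subject_id)) {
    dup <- df$subject_id[duplicated(df$subject_id)][1L]
    stop("duplicate subject_id: '", dup, "'")
  }
  conc <- matrix(NA_real_, nrow = length(markers), ncol = nrow(df),
                 dimnames = list(markers, df$subject_id))
  for (m in markers) {
    v <- suppressWarnings(as.numeric(df[[m]]))
    bad <- which(is.na(v) | v <= 0)
    if (length(bad)) {
      stop(sprintf(
        "invalid %s value '%s' for subject '%s': must be a positive number",
        m, df[[m]][bad[1L]], df$subject_id[bad[1L]]))
    }
    conc[m, ] <- v
  }
  stage <- suppressWarnings(as.integer(df$stage))
  isCase <- df$label == "case"
  noStage <- which(isCase & is.na(stage))
  if (length(noStage)) {
    stop("case '", df$subject_id[noStage[1L]], "' has no stage")
  }
  MarkerCohort(conc, age = suppressWarnings(as.numeric(df$age)),
               sex = df$sex, label = df$label, stage = stage)
}

#' Read a cohort generator config from YAML or JSON
#'
#' Parses a key-value file whose fields mirror [cohortConfig()] in
#' snake_case: \code{n_case}, \code{n_control}, \code{marker_names},
#' \code{control_log_mean}, \code{log_sd}, \code{effect_shift} (scalars
#' or per-marker maps), \code{stage_probs}, \code{stage_effect_scale},
#' \code{age_case_mean}, \code{age_case_sd}, \code{age_control_mean},
#' \code{age_control_sd}, \code{male_frac_case},
#' \code{male_frac_control}, \code{seed}. Omitted fields take the
#' defaults; unknown fields are an error.
#'
#' @param path A \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A \linkS4class{CohortConfig}.
#' @export
readCohortConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = read_json(path, simplifyVector = TRUE),
    stop("config must be a .yaml/.yml or .json file"))
  fieldMap <- c(n_case = "nCase", n_control = "nControl",
                marker_names = "markerNames",
                control_log_mean = "controlLogMean", log_sd = "logSd",
                effect_shift = "effectShift", stage_probs = "stageProbs",
                stage_effect_scale = "stageEffectScale",
                age_case_mean = "ageCaseMean", age_case_sd = "ageCaseSd",
                age_control_mean = "ageControlMean",
                age_control_sd = "ageControlSd",
                male_frac_case = "maleFracCase",
                male_frac_control = "maleFracControl", seed = "seed")
  unknown <- setdiff(names(raw), names(fieldMap))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  args <- lapply(raw, function(v) {
    if (is.list(v)) unlist(v) else v
  })
  names(args) <- fieldMap[names(raw)]
  do.call(cohortConfig, args)
}

#' Serialize a SelectionLedger as JSON
#'
#' Machine-readable form of the full audit trail: parameters, per-stage
#' counts and panel lists, the final panel, its performance records, and
#' the screen table. Identical ledgers serialize to identical bytes (no
#' timestamps), so determinism can be checked on the JSON itself.
#'
#' @param ledger A \linkS4class{SelectionLedger}.
#' @param pretty Indent the JSON (default \code{TRUE}).
#' @return A JSON string.
#' @export
ledgerToJSON <- function(ledger, pretty = TRUE) {
  stopifnot(is(ledger, "SelectionLedger"))
  finalId <- if (length(ledger@finalPanel)) panelId(ledger@finalPanel)
             else character(0)
  finalRecords <- ledger@records[ledger@records$panel %in% finalId, ,
                                 drop = FALSE]
  obj <- list(
    parameters = ledger@parameters,
    counts = as.list(cascadeCounts(ledger)),
    stages = ledger@stagePanels,
    final_panel = ledger@finalPanel,
    final_records = finalRecords,
    screen = ledger@screen)
  as.character(toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                      na = "null", pretty = pretty))
}

#' Write a SelectionLedger and its side tables
#'
#' Writes, under \code{dir}: \code{ledger.json} (see [ledgerToJSON()]),
#' \code{records.csv} (all performance records, long format),
#' \code{screen.csv}, \code{split.csv} (subject id and train/validation
#' assignment) and \code{summary.txt} (the human-readable cascade
#' summary).
#'
#' @param ledger A \linkS4class{SelectionLedger}.
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
writeLedger <- function(ledger, dir) {
  stopifnot(is(ledger, "SelectionLedger"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(ledgerToJSON(ledger), file.path(dir, "ledger.json"))
  write.csv(ledger@records, file.path(dir, "records.csv"),
            row.names = FALSE)
  write.csv(ledger@screen, file.path(dir, "screen.csv"),
            row.names = FALSE)
  write.csv(data.frame(subject_id = names(ledger@split),
                       split = unname(ledger@split)),
            file.path(dir, "split.csv"), row.names = FALSE)
  txt <- utils::capture.output(show(ledger))
  writeLines(txt, file.path(dir, "summary.txt"))
  invisible(dir)
}
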