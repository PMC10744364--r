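# Recording and subject-table IO: format dispatch and the BIDS-style
# cohort layout used by the study's data deposit.

#' Read a recording (EDF or EEGLAB SET)
#'
#' @param path File path. The format is taken from the extension unless
#'   given explicitly.
#' @param format `"EDF"`, `"SET"`, or `NULL` to infer from the extension.
#' @param normalize Normalize channel labels to canonical 10-20 names?
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = NULL, normalize = TRUE) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "EDF", set = "SET",
                     abort(sprintf("cannot infer format from extension '.%s'", ext),
                           "format_error"))
  }
  switch(toupper(format),
         EDF = read_edf(path, normalize = normalize),
         SET = read_set(path, normalize = normalize),
         abort(sprintf("unsupported format '%s'", format), "format_error"))
}

#' Read a subject table
#'
#' Tab-separated, header row required, UTF-8 (the BIDS participants.tsv
#' dialect). Required columns: `subject_id` (or `participant_id`),
#' `group`, `age`, `sex`; `mmse` is optional per row (empty allowed) but
#' the column must exist. Group values must be FTD or CTL (a leading
#' `A`/`C`/`F` BIDS coding of Alzheimer/control/FTD is mapped when
#' `recode_groups` covers it).
#'
#' @param path TSV file path.
#' @param recode_groups Named character vector mapping raw group codes to
#'   `"FTD"`/`"CTL"`.
#' @return Data frame (subject_id, group, age, sex, mmse) of class
#'   `subject_table`.
#' @export
read_subject_table <- function(path, recode_groups = c(F = "FTD", C = "CTL")) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "format_error")
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = c("", "n/a", "NA"))
  names(tab) <- tolower(names(tab))
  if ("participant_id" %in% names(tab) && !"subject_id" %in% names(tab))
    names(tab)[names(tab) == "participant_id"] <- "subject_id"
  needed <- c("subject_id", "group", "age", "sex", "mmse")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(missing, collapse = ", ")), "validation_error")
  tab <- tab[needed]
  raw_group <- as.character(tab$group)
  mapped <- ifelse(raw_group %in% names(recode_groups),
                   unname(recode_groups[raw_group]), raw_group)
  bad <- which(!mapped %in% c("FTD", "CTL"))
  if (length(bad))
    abort(sprintf("%s: row %d has unknown group '%s'", path, bad[1], raw_group[bad[1]]),
          "validation_error")
  tab$group <- mapped
  bad_mmse <- which(!is.na(tab$mmse) & (tab$mmse < 0 | tab$mmse > 30))
  if (length(bad_mmse))
    abort(sprintf("%s: row %d has MMSE %s outside [0, 30]", path, bad_mmse[1],
                  tab$mmse[bad_mmse[1]]), "validation_error")
  tab$mmse_missing <- is.na(tab$mmse)
  class(tab) <- c("subject_table", "data.frame")
  tab
}

#' Write a subject table
#'
#' @param subjects Data frame with subject_id, group, age, sex, mmse.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_subject_table <- function(subjects, path) {
  cols <- intersect(c("subject_id", "group", "age", "sex", "mmse"), names(subjects))
  utils::write.table(subjects[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from a directory
#'
#' Accepts either the flat layout written by [write_cohort()]
#' (`<id>.edf` + `participants.tsv`) or a BIDS-EEG style tree
#' (`sub-*/eeg/*_eeg.edf` or `.set` + `participants.tsv`).
#'
#' @param dir Cohort directory.
#' @return List with `recordings` and `subjects`, aligned by subject.
#' @export
read_cohort <- function(dir) {
  pt <- file.path(dir, "participants.tsv")
  if (!file.exists(pt))
    abort(sprintf("%s: participants.tsv not found", dir), "format_error")
  subjects <- read_subject_table(pt)
  recordings <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    id <- subjects$subject_id[i]
    candidates <- c(
      file.path(dir, paste0(id, ".edf")),
      file.path(dir, paste0(id, ".set")),
      Sys.glob(file.path(dir, id, "eeg", paste0(id, "*_eeg.edf"))),
      Sys.glob(file.path(dir, id, "eeg", paste0(id, "*_eeg.set"))))
    hit <- candidates[file.exists(candidates)]
    if (!length(hit))
      abort(sprintf("no recording found for subject %s under %s", id, dir),
            "format_error")
    recordings[[i]] <- read_recording(hit[1])
  }
  list(recordings = recordings, subjects = subjects)
}
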