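# Cytokine panel data model and delimited-text I/O.
#
# A panel is a subjects x features concentration matrix (pg/mL) plus subject
# metadata (sex, diagnosis) and an explicit missingness mask.  Features are
# named "CYTOKINE_Tk", e.g. "IL-10_T2", for cytokine measured at time point
# T0 (rest), T1 (peak effort) or T2 (4 h post exercise).

SEXES <- c("male", "female")
DIAGNOSES <- c("HC", "GWI", "CFS")
TIME_POINTS <- c("T0", "T1", "T2")

#' The 16-cytokine study panel
#'
#' Canonical cytokine list of the multiplex plasma assay: IL-1a, IL-1b, IL-2,
#' IL-4, IL-5, IL-6, IL-8, IL-10, IL-12p70, IL-13, IL-15, IL-17, IL-23,
#' IFNg, TNFa and TNFb.  Measured at three exercise time points this yields
#' the 48 candidate features of the classification workflow.
#'
#' @return character vector of 16 cytokine names.
#' @export
study_cytokines <- function() {
  c("IL-1a", "IL-1b", "IL-2", "IL-4", "IL-5", "IL-6", "IL-8", "IL-10",
    "IL-12p70", "IL-13", "IL-15", "IL-17", "IL-23", "IFNg", "TNFa", "TNFb")
}

#' Feature keys for a cytokine-by-time-point layout
#'
#' Expands cytokines and time points into feature names "CYTOKINE_Tk",
#' ordered cytokine-major with T0 < T1 < T2 within each cytokine.  This is
#' the deterministic column order used throughout the package.
#'
#' @param cytokines character vector of cytokine names.
#' @param time_points subset of `c("T0","T1","T2")`.
#' @return character vector of feature names.
#' @export
#' @examples
#' feature_keys(c("IL-2", "IL-23"), c("T0", "T1"))
feature_keys <- function(cytokines = study_cytokines(),
                         time_points = TIME_POINTS) {
  time_points <- match.arg(time_points, TIME_POINTS, several.ok = TRUE)
  time_points <- TIME_POINTS[TIME_POINTS %in% time_points]
  as.vector(t(outer(cytokines, time_points, paste, sep = "_")))
}

# split "IL-10_T2" into cytokine / time point; errors on unknown suffix
parse_feature_keys <- function(keys) {
  tp <- sub("^.*_", "", keys)
  bad <- !grepl("^.+_T[0-9]+$", keys) | !(tp %in% TIME_POINTS)
  if (any(bad)) {
    stop("feature column(s) with unknown time-point suffix: ",
         paste(keys[bad], collapse = ", "),
         " (expected names like 'IL-10_T2' with suffix T0/T1/T2)")
  }
  data.frame(feature = keys,
             cytokine = sub("_T[0-9]+$", "", keys),
             time_point = tp,
             stringsAsFactors = FALSE)
}

#' Construct a cytokine panel
#'
#' @param values numeric matrix, subjects x features, concentrations in
#'   pg/mL; `NA` marks missing cells.  Column names must follow the
#'   "CYTOKINE_Tk" convention; row names (or `subject_id`) label subjects.
#' @param sex character vector, one of `"male"`/`"female"` per subject.
#' @param diagnosis character vector, one of `"HC"`, `"GWI"`, `"CFS"`.
#' @param subject_id subject labels; defaults to the row names of `values`.
#' @param missing_mask optional logical matrix; defaults to `is.na(values)`.
#'   Cells flagged missing are stored as `NA` regardless of `values`.
#' @return an object of class `cytokine_panel`: a list with elements
#'   `values` (numeric matrix, `NA` at missing cells), `missing` (logical
#'   mask) and `subjects` (data frame with `subject_id`, `sex`,
#'   `diagnosis`).
#' @export
cytokine_panel <- function(values, sex, diagnosis,
                           subject_id = rownames(values),
                           missing_mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (is.null(subject_id)) stop("subject_id labels are required")
  subject_id <- as.character(subject_id)
  if (length(subject_id) != n || length(sex) != n || length(diagnosis) != n) {
    stop("subject_id, sex and diagnosis must each have one entry per row of values")
  }
  dup <- unique(subject_id[duplicated(subject_id)])
  if (length(dup)) stop("duplicate subject_id: ", paste(dup, collapse = ", "))
  sex <- as.character(sex)
  diagnosis <- as.character(diagnosis)
  if (!all(sex %in% SEXES)) {
    stop("sex must be one of: ", paste(SEXES, collapse = ", "))
  }
  if (!all(diagnosis %in% DIAGNOSES)) {
    stop("diagnosis must be one of: ", paste(DIAGNOSES, collapse = ", "))
  }
  if (is.null(colnames(values))) stop("values must have feature column names")
  parse_feature_keys(colnames(values))  # validates the suffix convention
  if (is.null(missing_mask)) {
    missing_mask <- is.na(values)
  } else {
    missing_mask <- as.matrix(missing_mask)
    if (!identical(dim(missing_mask), dim(values))) {
      stop("missing_mask must have the same dimensions as values")
    }
    missing_mask <- missing_mask | is.na(values)
  }
  values[missing_mask] <- NA_real_
  neg <- which(!missing_mask & values < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative concentration for subject '%s', feature '%s'",
                 subject_id[neg[1, 1]], colnames(values)[neg[1, 2]]))
  }
  rownames(values) <- subject_id
  dimnames(missing_mask) <- dimnames(values)
  structure(list(values = values,
                 missing = missing_mask,
                 subjects = data.frame(subject_id = subject_id,
                                       sex = sex,
                                       diagnosis = diagnosis,
                                       stringsAsFactors = FALSE)),
            class = "cytokine_panel")
}

#' @export
print.cytokine_panel <- function(x, ...) {
  tab <- table(x$subjects$sex, x$subjects$diagnosis)
  cat(sprintf("<cytokine_panel> %d subjects x %d features (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(x$missing)))
  print(tab)
  invisible(x)
}

#' Feature metadata of a panel
#'
#' @param panel a `cytokine_panel`.
#' @return data frame with columns `feature`, `cytokine`, `time_point` in
#'   panel column order.
#' @export
panel_features <- function(panel) {
  stopifnot(inherits(panel, "cytokine_panel"))
  parse_feature_keys(colnames(panel$values))
}

#' Read a cytokine panel from delimited text
#'
#' Expects a header row with columns `subject_id`, `sex`, `diagnosis` and
#' one column per feature named "CYTOKINE_Tk".  Empty cells denote missing
#' values; any other non-numeric cell is an error (never silently missing).
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, anything
#'   else comma-separated unless `sep` is given.
#' @param sep field separator override.
#' @return a [cytokine_panel()].
#' @export
read_panel <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = character(),
                           quote = "\"", comment.char = "")
  req <- c("subject_id", "sex", "diagnosis")
  absent <- setdiff(req, names(raw))
  if (length(absent)) {
    stop("panel file is missing required column(s): ",
         paste(absent, collapse = ", "))
  }
  feats <- setdiff(names(raw), req)
  if (!length(feats)) stop("panel file has no feature columns")
  parse_feature_keys(feats)
  vals <- matrix(NA_real_, nrow(raw), length(feats),
                 dimnames = list(raw$subject_id, feats))
  for (j in seq_along(feats)) {
    cell <- trimws(raw[[feats[j]]])
    empty <- is.na(cell) | cell == ""
    v <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(v))
    if (length(bad)) {
      stop(sprintf("unparseable numeric value '%s' (subject '%s', feature '%s')",
                   cell[bad[1]], raw$subject_id[bad[1]], feats[j]))
    }
    vals[, j] <- v
  }
  cytokine_panel(vals, sex = raw$sex, diagnosis = raw$diagnosis,
                 subject_id = raw$subject_id)
}

#' Write a cytokine panel to delimited text
#'
#' Values are written with 17 significant digits so that
#' `read_panel(write_panel(p))` round-trips bit-exactly; missing cells are
#' written empty.
#'
#' @param panel a `cytokine_panel`.
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, sep = ",") {
  stopifnot(inherits(panel, "cytokine_panel"))
  chr <- matrix("", nrow(panel$values), ncol(panel$values),
                dimnames = dimnames(panel$values))
  ok <- !panel$missing
  chr[ok] <- sprintf("%.17g", panel$values[ok])
  out <- cbind(panel$subjects, as.data.frame(chr, stringsAsFactors = FALSE,
                                             check.names = FALSE))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assert the 16 x 3 study layout
#'
#' The replication workflow expects the full 16-cytokine, 3-time-point
#' feature set (48 columns); arbitrary panels are accepted elsewhere.
#'
#' @param panel a `cytokine_panel`.
#' @return the panel, invisibly, or an error.
#' @export
assert_study_panel <- function(panel) {
  keys <- feature_keys()
  have <- colnames(panel$values)
  if (length(have) != 48L || !setequal(have, keys)) {
    stop("study workflow expects the 48-feature panel (16 cytokines x T0/T1/T2); got ",
         length(have), " features")
  }
  invisible(panel)
}

#' Extract a two-group feature matrix from a panel
#'
#' Builds the design matrix for one comparison: either two diagnosis groups
#' (optionally within one sex) or male vs female within one diagnosis.
#' Columns are ordered deterministically by (cytokine order of the panel,
#' T0 < T1 < T2); the second-listed group is the "positive" class (group J)
#' coded 1.
#'
#' @param panel a `cytokine_panel`.
#' @param diagnoses character pair, e.g. `c("HC","GWI")`, to compare
#'   diagnosis groups (group J = second entry).
#' @param sexes character pair, e.g. `c("male","female")`, to compare sexes.
#'   Exactly one of `diagnoses`/`sexes` must be a pair.
#' @param sex optional single sex filter when comparing diagnoses.
#' @param diagnosis optional single diagnosis filter when comparing sexes.
#' @param time_points subset of time points to retain.
#' @return list with `X` (numeric matrix), `y` (factor, levels = the pair,
#'   second level positive), `y01` (0/1 integer), `mask` (missingness),
#'   `features` (feature metadata), `groups`, `positive`.
#' @export
select_cohort <- function(panel, diagnoses = NULL, sexes = NULL,
                          sex = NULL, diagnosis = NULL,
                          time_points = TIME_POINTS) {
  stopifnot(inherits(panel, "cytokine_panel"))
  time_points <- match.arg(time_points, TIME_POINTS, several.ok = TRUE)
  meta <- panel$subjects
  keep <- rep(TRUE, nrow(meta))
  if (xor(length(diagnoses) == 2L, length(sexes) == 2L) == FALSE) {
    stop("supply exactly one comparison pair: diagnoses or sexes")
  }
  if (length(diagnoses) == 2L) {
    if (!is.null(sex)) keep <- keep & meta$sex == sex
    keep <- keep & meta$diagnosis %in% diagnoses
    grp <- meta$diagnosis
    pair <- diagnoses
    stratum <- function(g) {
      paste0(if (!is.null(sex)) paste0("sex=", sex, ", ") else "",
             "diagnosis=", g)
    }
  } else {
    if (!is.null(diagnosis)) keep <- keep & meta$diagnosis == diagnosis
    keep <- keep & meta$sex %in% sexes
    grp <- meta$sex
    pair <- sexes
    stratum <- function(g) {
      paste0("sex=", g,
             if (!is.null(diagnosis)) paste0(", diagnosis=", diagnosis) else "")
    }
  }
  for (g in pair) {
    if (!any(keep & grp == g)) {
      stop("no subjects in stratum ", stratum(g))
    }
  }
  finfo <- panel_features(panel)
  cyto_order <- unique(finfo$cytokine)
  cols <- character(0)
  for (cy in cyto_order) {
    for (tp in TIME_POINTS[TIME_POINTS %in% time_points]) {
      key <- paste0(cy, "_", tp)
      if (key %in% finfo$feature) cols <- c(cols, key)
    }
  }
  X <- panel$values[keep, cols, drop = FALSE]
  mask <- panel$missing[keep, cols, drop = FALSE]
  y <- factor(grp[keep], levels = pair)
  list(X = X, y = y, y01 = as.integer(y) - 1L, mask = mask,
       features = parse_feature_keys(cols), groups = pair,
       positive = pair[2L])
}
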