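#' Molecular and histologic markers for integrated diagnosis
#'
#' Collects the markers that drive the 2021 WHO classification of
#' adult-type diffuse gliomas. Any marker may be `NA` (unknown); unknown
#' markers on a decisive path propagate to an `unresolved` outcome rather
#' than silently defaulting. A 1p/19q codeletion without an IDH mutation is
#' not a valid adult-type diffuse-glioma record and is flagged with a
#' warning.
#'
#' @param idh_mutant IDH1/IDH2 hotspot mutation present.
#' @param codel_1p19q Combined whole-arm 1p/19q codeletion.
#' @param cdkn2ab_homdel CDKN2A/B homozygous deletion.
#' @param tert_promoter_mutant TERT promoter mutation.
#' @param egfr_amplified High-level EGFR amplification (not low-level gains).
#' @param plus7_minus10 Whole chromosome 7 gain AND whole chromosome 10 loss.
#' @param mvp Microvascular proliferation (histology).
#' @param necrosis Necrosis (histology).
#' @param histologic_grade Pre-molecular histologic impression, 2 or 3.
#' @return Object of class `diagnostic_markers`.
#' @export
diagnostic_markers <- function(idh_mutant = NA, codel_1p19q = NA,
                               cdkn2ab_homdel = NA, tert_promoter_mutant = NA,
                               egfr_amplified = NA, plus7_minus10 = NA,
                               mvp = NA, necrosis = NA, histologic_grade = NA) {
  chk <- function(x, nm) {
    if (!is.na(x) && !is.logical(x)) stop_invalid(nm, " must be TRUE/FALSE/NA")
    as.logical(x)
  }
  m <- list(idh_mutant = chk(idh_mutant, "idh_mutant"),
            codel_1p19q = chk(codel_1p19q, "codel_1p19q"),
            cdkn2ab_homdel = chk(cdkn2ab_homdel, "cdkn2ab_homdel"),
            tert_promoter_mutant = chk(tert_promoter_mutant, "tert_promoter_mutant"),
            egfr_amplified = chk(egfr_amplified, "egfr_amplified"),
            plus7_minus10 = chk(plus7_minus10, "plus7_minus10"),
            mvp = chk(mvp, "mvp"), necrosis = chk(necrosis, "necrosis"),
            histologic_grade = if (is.na(histologic_grade)) NA_integer_
                               else as.integer(histologic_grade))
  if (!is.na(m$histologic_grade) && !m$histologic_grade %in% c(2L, 3L))
    stop_invalid("histologic_grade must be 2 or 3")
  if (isTRUE(m$codel_1p19q) && isFALSE(m$idh_mutant))
    warning("1p/19q codeletion without IDH mutation: not a valid ",
            "adult-type diffuse-glioma record")
  structure(m, class = "diagnostic_markers")
}

unresolved <- function(markers_missing, rationale) {
  structure(list(status = "unresolved", type = NA_character_,
                 grade = NA_integer_, category = NA_character_,
                 missing = markers_missing, rationale = rationale),
            class = "integrated_diagnosis")
}

classified <- function(type, grade, rationale) {
  category <- if (type == "GBM") "GBM" else paste0(type, grade)
  structure(list(status = "classified", type = type, grade = as.integer(grade),
                 category = category, missing = character(),
                 rationale = rationale), class = "integrated_diagnosis")
}

#' Integrated 2021-WHO diagnosis of an adult-type diffuse glioma
#'
#' Deterministic rule engine mapping [diagnostic_markers()] to one of the
#' six categories A2, A3, A4, O2, O3, GBM. Rule order:
#' \enumerate{
#'   \item IDH-mutant and 1p/19q-codeleted: oligodendroglioma, grade =
#'     histologic grade (O2/O3).
#'   \item IDH-mutant, non-codeleted: astrocytoma; grade 4 iff
#'     microvascular proliferation, necrosis, or CDKN2A/B homozygous
#'     deletion (any combination), else the histologic grade (A2/A3).
#'   \item IDH-wildtype: glioblastoma iff the histologic high-grade picture
#'     (`histology_rule`) or a molecular GBM criterion — TERT promoter
#'     mutation, high-level EGFR amplification, or +7/-10 — holds,
#'     regardless of a grade 2/3 histologic appearance.
#' }
#' An IDH-wildtype tumor with no qualifying feature is returned as
#' `indeterminate` (not classifiable as an adult-type diffuse glioma in this
#' scheme, not an error). An unknown marker on the decisive path yields an
#' `unresolved` outcome naming the missing marker(s).
#'
#' @param m A [diagnostic_markers()].
#' @param histology_rule For the IDH-wildtype histologic qualification:
#'   `"either"` (default; MVP or necrosis) or `"both"` (MVP and necrosis).
#' @return Object of class `integrated_diagnosis` with `status`
#'   (`classified` / `indeterminate` / `unresolved`), `type` (A/O/GBM),
#'   `grade`, `category`, `missing`, and `rationale` (ordered fired rules).
#' @export
integrate_diagnosis <- function(m, histology_rule = c("either", "both")) {
  histology_rule <- match.arg(histology_rule)
  stopifnot(inherits(m, "diagnostic_markers"))
  if (is.na(m$idh_mutant))
    return(unresolved("idh_mutant", "IDH status unknown: cannot enter the scheme"))
  if (m$idh_mutant) {
    if (is.na(m$codel_1p19q))
      return(unresolved("codel_1p19q",
                        "IDH-mutant: 1p/19q status decides A vs O"))
    if (m$codel_1p19q) {
      if (is.na(m$histologic_grade))
        return(unresolved("histologic_grade",
                          "oligodendroglioma grade needs the histologic grade"))
      return(classified("O", m$histologic_grade, c(
        "IDH-mutant + 1p/19q codeleted: oligodendroglioma",
        paste0("histologic grade ", m$histologic_grade))))
    }
    g4 <- c(mvp = m$mvp, necrosis = m$necrosis, cdkn2ab_homdel = m$cdkn2ab_homdel)
    if (any(g4, na.rm = TRUE)) {
      fired <- names(g4)[which(g4)]
      return(classified("A", 4L, c(
        "IDH-mutant, non-codeleted: astrocytoma",
        paste0("grade 4 by ", paste(fired, collapse = " + ")))))
    }
    if (anyNA(g4))
      return(unresolved(names(g4)[is.na(g4)],
                        "astrocytoma grade-4 qualifiers incompletely known"))
    if (is.na(m$histologic_grade))
      return(unresolved("histologic_grade",
                        "astrocytoma grade needs the histologic grade"))
    return(classified("A", m$histologic_grade, c(
      "IDH-mutant, non-codeleted: astrocytoma",
      "no grade-4 qualifier",
      paste0("histologic grade ", m$histologic_grade))))
  }
  # IDH-wildtype
  histo <- if (histology_rule == "either") {
    if (isTRUE(m$mvp) || isTRUE(m$necrosis)) TRUE
    else if (is.na(m$mvp) || is.na(m$necrosis)) NA else FALSE
  } else {
    if (isFALSE(m$mvp) || isFALSE(m$necrosis)) FALSE
    else if (is.na(m$mvp) || is.na(m$necrosis)) NA else TRUE
  }
  mol <- c(tert_promoter_mutant = m$tert_promoter_mutant,
           egfr_amplified = m$egfr_amplified, plus7_minus10 = m$plus7_minus10)
  quals <- c(histologic_picture = histo, mol)
  if (any(quals, na.rm = TRUE)) {
    fired <- names(quals)[which(quals)]
    return(classified("GBM", 4L, c(
      "IDH-wildtype",
      paste0("GBM by ", paste(fired, collapse = " + ")))))
  }
  if (anyNA(quals)) {
    miss <- names(quals)[is.na(quals)]
    miss[miss == "histologic_picture"] <- "mvp/necrosis"
    return(unresolved(miss, "IDH-wildtype GBM qualifiers incompletely known"))
  }
  structure(list(status = "indeterminate", type = NA_character_,
                 grade = NA_integer_, category = NA_character_,
                 missing = character(),
                 rationale = c("IDH-wildtype", "no qualifying feature",
                               "not classifiable as adult-type diffuse glioma in this scheme")),
            class = "integrated_diagnosis")
}

#' @export
print.integrated_diagnosis <- function(x, ...) {
  cat("<integrated_diagnosis>", x$status,
      if (x$status == "classified") paste0(x$category, " (type ", x$type,
                                           ", grade ", x$grade, ")"),
      "\n  ", paste(x$rationale, collapse = "; "), "\n")
  invisible(x)
}

#' Classify a marker table
#'
#' Applies [integrate_diagnosis()] row-wise to a marker table (one patient
#' per row; boolean columns as `true`/`false`/`unknown` when read from CSV).
#'
#' @param df Data frame with the [diagnostic_markers()] columns and
#'   optionally `patient_id`.
#' @inheritParams integrate_diagnosis
#' @return Data frame: `patient_id`, `status`, `type`, `grade`, `category`,
#'   `rationale` (collapsed with "; ").
#' @export
classify_marker_table <- function(df, histology_rule = c("either", "both")) {
  histology_rule <- match.arg(histology_rule)
  ids <- if ("patient_id" %in% names(df)) as.character(df$patient_id)
         else as.character(seq_len(nrow(df)))
  rows <- lapply(seq_len(nrow(df)), function(i) {
    args <- as.list(df[i, intersect(names(df), names(formals(diagnostic_markers)))])
    d <- integrate_diagnosis(do.call(diagnostic_markers, args), histology_rule)
    data.frame(patient_id = ids[i], status = d$status, type = d$type,
               grade = d$grade, category = d$category,
               rationale = paste(d$rationale, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read / write a diagnostic marker table CSV
#'
#' Boolean marker columns use `true`/`false`/`unknown` (case-insensitive;
#' empty cells also read as unknown).
#'
#' @param path CSV path.
#' @export
read_marker_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  bools <- setdiff(names(formals(diagnostic_markers)), "histologic_grade")
  for (cl in intersect(bools, names(df))) {
    v <- tolower(trimws(df[[cl]]))
    df[[cl]] <- ifelse(v %in% c("true", "t", "1"), TRUE,
                       ifelse(v %in% c("false", "f", "0"), FALSE, NA))
  }
  if ("histologic_grade" %in% names(df))
    df$histologic_grade <- suppressWarnings(as.integer(df$histologic_grade))
  df
}

#' @rdname read_marker_table
#' @param df Marker data frame.
#' @export
write_marker_table <- function(df, path) {
  out <- df
  bools <- setdiff(names(formals(diagnostic_markers)), "histologic_grade")
  for (cl in intersect(bools, names(out)))
    out[[cl]] <- ifelse(is.na(out[[cl]]), "unknown",
                        ifelse(out[[cl]], "true", "false"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
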