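#' Multireference classification thresholds for I_ND^max
#'
#' Default threshold table translating the Nielsen-Janssen D2 boundaries
#' (0.15 safe; 0.17 MP2 / 0.18 CCSD multireference) into I_ND^max values via
#' the fitted equivalences: below `lower` a system is non-MR, at or above
#' `upper` it is MR, in between it deserves caution.
#'
#' The default `"mp2"` row carries the largest-set fit (5090 molecules,
#' 0.030/0.037); the small-set alternative (34 molecules, 0.029/0.037) ships
#' as `"mp2-setc"`.  `"ccsd"` uses 0.024/0.034, identical across the small
#' and large fitting sets.
#'
#' @return A data frame of class `"threshold_table"` with columns `method`,
#'   `lower`, `upper`, `note`.
#' @examples
#' default_thresholds()
#' @seealso [classify_mr()], [threshold_table()]
#' @export
default_thresholds <- function() {
  threshold_table(
    method = c("mp2", "mp2-setc", "ccsd"),
    lower = c(0.030, 0.029, 0.024),
    upper = c(0.037, 0.037, 0.034),
    note = c("MP2 fit, 5090-molecule set (D2 0.15/0.17)",
             "MP2 fit, 34-molecule Nielsen-Janssen set (D2 0.15/0.17)",
             "CCSD fit, 14- and 311-molecule sets agree (D2 0.15/0.18)"))
}

#' Build a threshold table
#'
#' @param method character vector of method names (matched case-insensitively).
#' @param lower numeric: below this value a system is classified non-MR.
#' @param upper numeric: at or above this value a system is classified MR.
#' @param note provenance notes.
#' @return A data frame of class `"threshold_table"`.
#' @examples
#' threshold_table("casscf-like", 0.02, 0.05, "user calibration")
#' @export
threshold_table <- function(method, lower, upper, note = "") {
  stopifnot(length(method) == length(lower), length(lower) == length(upper))
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
    nd_stop("noodiag_invalid_thresholds",
            "threshold table requires finite lower < upper for every method")
  structure(
    data.frame(method = tolower(as.character(method)),
               lower = as.numeric(lower), upper = as.numeric(upper),
               note = rep_len(as.character(note), length(method)),
               stringsAsFactors = FALSE),
    class = c("threshold_table", "data.frame"))
}

#' Read a threshold table from JSON
#'
#' Accepts a JSON array of objects with fields `method`, `lower`, `upper`
#' and optional `note`, mirroring [threshold_table()].
#'
#' @param path file path.
#' @return A `"threshold_table"`.
#' @export
read_threshold_table <- function(path) {
  rec <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e)
                    nd_stop("noodiag_format_error",
                            "cannot parse threshold JSON '%s': %s", path,
                            conditionMessage(e)))
  if (is.null(rec$method) || is.null(rec$lower) || is.null(rec$upper))
    nd_stop("noodiag_format_error",
            "threshold JSON '%s' must provide method/lower/upper fields", path)
  threshold_table(rec$method, rec$lower, rec$upper,
                  if (is.null(rec$note)) "" else rec$note)
}

#' Classify multireference character from I_ND^max
#'
#' @param i_nd_max the maximal single-orbital nondynamic contribution, in
#'   \eqn{[0, 1/8]} (see [nd_max()]).
#' @param method method name present in `table` (case-insensitive).
#' @param table a [threshold_table()].
#' @return `"non-MR"` (below the lower threshold), `"MR"` (at/above the
#'   upper threshold) or `"caution"` (in between).
#' @examples
#' classify_mr(0.020, "mp2")   # non-MR
#' classify_mr(0.040, "mp2")   # MR
#' classify_mr(0.030, "ccsd")  # caution
#' @export
classify_mr <- function(i_nd_max, method, table = default_thresholds()) {
  stopifnot(is.numeric(i_nd_max), length(i_nd_max) == 1)
  if (!is.finite(i_nd_max) || i_nd_max < -1e-12 || i_nd_max > 0.125 + 1e-9)
    nd_stop("noodiag_range_error",
            "i_nd_max = %g outside its range [0, 1/8]", i_nd_max)
  row <- table[table$method == tolower(method), , drop = FALSE]
  if (nrow(row) == 0)
    nd_stop("noodiag_missing_threshold",
            "no thresholds for method '%s'; add a user-defined row via threshold_table()",
            method)
  row <- row[1, ]
  if (i_nd_max < row$lower) "non-MR"
  else if (i_nd_max >= row$upper) "MR"
  else "caution"
}
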