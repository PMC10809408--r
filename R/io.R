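#' Read natural orbital occupancies from a file
#'
#' Supported formats:
#' \describe{
#'   \item{molden}{occupations parsed from the `Occup=` fields of the
#'     `[MO]` section; when both `Spin= Alpha` and `Spin= Beta` orbitals are
#'     present the file is treated as spin-resolved (occupations in
#'     \eqn{[0, 1]}), otherwise as spatial (occupations in \eqn{[0, 2]}).}
#'   \item{wfx}{numbers inside the
#'     `<Molecular Orbital Occupation Numbers>` block (spatial convention).}
#'   \item{plain}{one number per line; `#` comments and blank lines are
#'     ignored.  Spatial unless `spin_resolved = TRUE`, in which case two
#'     blocks separated by a blank line (or a single block reused for both
#'     channels) are read as alpha/beta.}
#'   \item{json}{either `{"occ": [...], "n_electrons": N}` or
#'     `{"occ_alpha": [...], "occ_beta": [...], "n_alpha": ..,
#'     "n_beta": ..}`, each count optional.}
#'   \item{auto}{sniffed from the content; the decision is reported via
#'     `message()`.}
#' }
#' Scientific notation (including Fortran `D` exponents) is accepted and
#' parsing is locale-independent.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"molden"`, `"wfx"`, `"plain"`, `"json"`.
#' @param n_electrons optional explicit electron count (total for spatial
#'   input); inferred from the occupation sum when absent.
#' @param spin_resolved treat plain-text input as spin-resolved.
#' @return An object of class `"occupancy_file_record"`: `occupancies`
#'   (a [closed_shell_occupancies()] or [spin_occupancy_set()]),
#'   `source_format`, `source_path`, `warnings`.
#' @examples
#' p <- tempfile(fileext = ".txt")
#' writeLines(c("2.0", "0.0"), p)
#' read_occupancies(p)$occupancies
#' @export
read_occupancies <- function(path, format = c("auto", "molden", "wfx",
                                              "plain", "json"),
                             n_electrons = NULL, spin_resolved = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path))
    nd_stop("noodiag_format_error", "file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines))))
    nd_stop("noodiag_format_error", "file '%s' is empty", path)
  if (format == "auto") {
    format <- sniff_format(lines)
    message(sprintf("read_occupancies: '%s' detected as %s", path, format))
  }
  warn <- character(0)
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
  })
  occ <- switch(format,
    molden = wh(parse_molden(lines, path, n_electrons)),
    wfx = wh(parse_wfx(lines, path, n_electrons)),
    plain = wh(parse_plain(lines, path, n_electrons, spin_resolved)),
    json = wh(parse_occ_json(path, n_electrons)))
  for (w in warn) warning(w, call. = FALSE)
  structure(list(occupancies = occ, source_format = format,
                 source_path = path, warnings = warn),
            class = "occupancy_file_record")
}

#' @export
print.occupancy_file_record <- function(x, ...) {
  cat(sprintf("<occupancy_file_record> %s (%s)\n", x$source_path,
              x$source_format))
  print(x$occupancies)
  invisible(x)
}

sniff_format <- function(lines) {
  if (any(grepl("\\[MO\\]", lines, ignore.case = TRUE))) return("molden")
  if (any(grepl("<Molecular Orbital Occupation Numbers>", lines, fixed = TRUE)))
    return("wfx")
  first <- trimws(lines[nzchar(trimws(lines))][1])
  if (startsWith(first, "{") || startsWith(first, "[")) return("json")
  "plain"
}

# locale-safe numeric parse accepting Fortran D exponents
parse_num <- function(x, path, lineno) {
  v <- suppressWarnings(as.numeric(gsub("[dD]([+-]?[0-9])", "e\\1", x)))
  if (any(is.na(v)))
    nd_stop("noodiag_format_error",
            "cannot parse number '%s' at line %d of '%s'",
            x[which(is.na(v))[1]], lineno, path)
  v
}

parse_molden <- function(lines, path, n_el) {
  mo <- grep("^\\s*\\[MO\\]\\s*$", lines, ignore.case = TRUE)
  if (!length(mo))
    nd_stop("noodiag_format_error", "no [MO] section in '%s'", path)
  sec_end <- grep("^\\s*\\[", lines)
  sec_end <- c(sec_end[sec_end > mo[1]], length(lines) + 1L)[1] - 1L
  body <- (mo[1] + 1L):sec_end
  occ_lines <- grep("^\\s*Occup\\s*=", lines[body], ignore.case = TRUE)
  if (!length(occ_lines))
    nd_stop("noodiag_format_error",
            "no Occup= fields in the [MO] section of '%s'", path)
  occ <- vapply(occ_lines, function(i) {
    parse_num(trimws(sub("^\\s*Occup\\s*=", "", lines[body][i],
                         ignore.case = TRUE)), path, body[i])
  }, numeric(1))
  spin_lines <- grep("^\\s*Spin\\s*=", lines[body], ignore.case = TRUE)
  spins <- toupper(trimws(sub("^\\s*Spin\\s*=", "",
                              lines[body][spin_lines], ignore.case = TRUE)))
  if (length(spins) == length(occ) && any(spins == "BETA")) {
    spin_occupancy_set(occ[spins == "ALPHA"], occ[spins == "BETA"],
                       label = basename(path))
  } else {
    closed_shell_occupancies(occ, n_electrons = n_el, label = basename(path))
  }
}

parse_wfx <- function(lines, path, n_el) {
  open <- grep("<Molecular Orbital Occupation Numbers>", lines, fixed = TRUE)
  close <- grep("</Molecular Orbital Occupation Numbers>", lines, fixed = TRUE)
  if (!length(open) || !length(close) || close[1] <= open[1])
    nd_stop("noodiag_format_error",
            "no <Molecular Orbital Occupation Numbers> block in '%s'", path)
  body <- lines[(open[1] + 1L):(close[1] - 1L)]
  toks <- unlist(strsplit(trimws(body[nzchar(trimws(body))]), "\\s+"))
  if (!length(toks))
    nd_stop("noodiag_format_error",
            "empty occupation block at line %d of '%s'", open[1] + 1L, path)
  closed_shell_occupancies(parse_num(toks, path, open[1] + 1L),
                           n_electrons = n_el, label = basename(path))
}

parse_plain <- function(lines, path, n_el, spin_resolved) {
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!spin_resolved) {
    toks <- unlist(strsplit(trimws(lines[keep]), "\\s+"))
    if (!length(toks))
      nd_stop("noodiag_format_error", "no numeric content in '%s'", path)
    return(closed_shell_occupancies(parse_num(toks, path, which(keep)[1]),
                                    n_electrons = n_el,
                                    label = basename(path)))
  }
  # spin-resolved plain text: alpha block, blank line, beta block
  body <- lines[!grepl("^\\s*#", lines)]
  blank <- which(!nzchar(trimws(body)))
  first_blank <- blank[blank > 1 & blank < length(body)][1]
  if (is.na(first_blank)) {
    occ <- parse_num(trimws(body[nzchar(trimws(body))]), path, 1L)
    return(spin_occupancy_set(occ, occ, label = basename(path)))
  }
  occ_a <- parse_num(trimws(body[seq_len(first_blank - 1L)]), path, 1L)
  rest <- body[(first_blank + 1L):length(body)]
  occ_b <- parse_num(trimws(rest[nzchar(trimws(rest))]), path, first_blank + 1L)
  spin_occupancy_set(occ_a, occ_b, label = basename(path))
}

parse_occ_json <- function(path, n_el) {
  rec <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e)
                    nd_stop("noodiag_format_error",
                            "cannot parse JSON '%s': %s", path,
                            conditionMessage(e)))
  if (!is.null(rec$occ_alpha)) {
    spin_occupancy_set(rec$occ_alpha,
                       if (is.null(rec$occ_beta)) rec$occ_alpha else rec$occ_beta,
                       n_alpha = rec$n_alpha, n_beta = rec$n_beta,
                       label = if (is.null(rec$label)) basename(path) else rec$label)
  } else if (!is.null(rec$occ)) {
    closed_shell_occupancies(rec$occ,
                             n_electrons = if (is.null(n_el)) rec$n_electrons else n_el,
                             label = if (is.null(rec$label)) basename(path) else rec$label)
  } else {
    nd_stop("noodiag_format_error",
            "JSON '%s' has neither 'occ' nor 'occ_alpha' fields", path)
  }
}

# full-precision numeric formatting shared by every writer
fmt17 <- function(x) formatC(x, digits = 17, format = "g")

#' Write occupancy fixture files
#'
#' Minimal valid writers for each supported occupancy format, used by the
#' `fixtures` CLI subcommand and the round-trip tests.  Occupations are
#' written at full double precision so read-back is exact.
#'
#' @param x an occupancy set (spatial sets for `wfx`; either for the rest).
#' @param path output path.
#' @return `path`, invisibly.
#' @name occupancy_writers
NULL

#' @rdname occupancy_writers
#' @export
write_molden_occupancies <- function(x, path) {
  lines <- c("[Molden Format]", "[Atoms] AU", "[MO]")
  if (inherits(x, "spin_occupancy_set")) {
    block <- function(occ, spin) unlist(lapply(seq_along(occ), function(i)
      c(sprintf(" Sym= a%d", i), sprintf(" Ene= %d.0", i),
        sprintf(" Spin= %s", spin), sprintf(" Occup= %s", fmt17(occ[i])))))
    lines <- c(lines, block(x$occ_alpha, "Alpha"), block(x$occ_beta, "Beta"))
  } else {
    lines <- c(lines, unlist(lapply(seq_along(x$occ), function(i)
      c(sprintf(" Sym= a%d", i), sprintf(" Ene= %d.0", i), " Spin= Alpha",
        sprintf(" Occup= %s", fmt17(x$occ[i]))))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname occupancy_writers
#' @export
write_wfx_occupancies <- function(x, path) {
  if (!inherits(x, "closed_shell_occupancy_set"))
    nd_stop("noodiag_format_error",
            "wfx writer expects a closed-shell (spatial) occupancy set")
  writeLines(c("<Number of Occupied Molecular Orbitals>",
               sprintf(" %d", length(x$occ)),
               "</Number of Occupied Molecular Orbitals>",
               "<Molecular Orbital Occupation Numbers>",
               sprintf(" %s", fmt17(x$occ)),
               "</Molecular Orbital Occupation Numbers>"), path)
  invisible(path)
}

#' @rdname occupancy_writers
#' @export
write_plain_occupancies <- function(x, path) {
  if (inherits(x, "spin_occupancy_set")) {
    writeLines(c("# alpha", fmt17(x$occ_alpha), "", "# beta",
                 fmt17(x$occ_beta)), path)
  } else {
    writeLines(fmt17(x$occ), path)
  }
  invisible(path)
}

#' @rdname occupancy_writers
#' @export
write_json_occupancies <- function(x, path) {
  rec <- if (inherits(x, "spin_occupancy_set"))
    list(occ_alpha = x$occ_alpha, occ_beta = x$occ_beta,
         n_alpha = x$n_alpha, n_beta = x$n_beta, label = x$label)
  else list(occ = x$occ, n_electrons = x$n_electrons, label = x$label)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Plain-text container for doubles amplitudes
#'
#' Serializes an [amplitude_set()] as a JSON document with fields `n_occ`,
#' `n_vir` and `t2` (column-major flattening of the `(i, j, a, b)` array,
#' full precision), the package's portable amplitude exchange format.
#'
#' @param t an [amplitude_set()].
#' @param path file path (conventionally `*.t2.json`).
#' @return `path` (writer, invisibly) / an [amplitude_set()] (reader).
#' @export
write_amplitudes <- function(t, path) {
  stopifnot(inherits(t, "amplitude_set"))
  jsonlite::write_json(list(n_occ = t$n_occ, n_vir = t$n_vir,
                            order = "column-major (i, j, a, b)",
                            t2 = as.numeric(t$t2)),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_amplitudes
#' @export
read_amplitudes <- function(path) {
  rec <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e)
                    nd_stop("noodiag_format_error",
                            "cannot parse amplitude container '%s': %s", path,
                            conditionMessage(e)))
  if (is.null(rec$n_occ) || is.null(rec$n_vir) || is.null(rec$t2))
    nd_stop("noodiag_format_error",
            "amplitude container '%s' must provide n_occ, n_vir, t2", path)
  no <- as.integer(rec$n_occ); nv <- as.integer(rec$n_vir)
  if (length(rec$t2) != no * no * nv * nv)
    nd_stop("noodiag_format_error",
            "amplitude container '%s': %d values, expected %d", path,
            length(rec$t2), no * no * nv * nv)
  amplitude_set(array(as.numeric(rec$t2), c(no, no, nv, nv)))
}

#' Write correlation reports to CSV or JSON
#'
#' Fixed, documented column order: `label`, `i_nd`, `i_d`, `i_t`,
#' `i_nd_hat`, `i_d_hat`, `i_nd_hat_occ`, `i_nd_hat_vir`, `i_nd_max`,
#' `ph_asymmetry`, `method`, `classification`; one row per system, input
#' order preserved.  CSV rounds floating values to 6 significant digits;
#' JSON keeps full precision so it round-trips exactly.  Output is
#' deterministic for identical input.
#'
#' @param reports a `"correlation_report"` or a list of them.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(reports, "correlation_report")) reports <- list(reports)
  if (!length(reports))
    nd_stop("noodiag_degenerate_input", "empty report list")
  df <- do.call(rbind, lapply(reports, report_row))
  if (format == "csv") {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    ok <- tryCatch({
      suppressWarnings(utils::write.csv(df, path, row.names = FALSE))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) nd_stop("noodiag_io_error", "cannot write '%s'", path)
  } else {
    ok <- tryCatch({
      suppressWarnings(jsonlite::write_json(df, path, auto_unbox = TRUE,
                                            digits = I(17),
                                            dataframe = "rows"))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) nd_stop("noodiag_io_error", "cannot write '%s'", path)
  }
  invisible(path)
}

report_row <- function(r) {
  data.frame(label = r$label, i_nd = r$i_nd, i_d = r$i_d, i_t = r$i_t,
             i_nd_hat = r$i_nd_hat, i_d_hat = r$i_d_hat,
             i_nd_hat_occ = r$i_nd_hat_occ, i_nd_hat_vir = r$i_nd_hat_vir,
             i_nd_max = r$i_nd_max, ph_asymmetry = r$ph_asymmetry,
             method = r$method, classification = r$classification,
             stringsAsFactors = FALSE)
}

#' Read correlation reports back from write_report output
#'
#' @param path a file written by [write_report()].
#' @param format `"csv"` or `"json"`.
#' @return A data frame in the documented column order.
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") utils::read.csv(path, stringsAsFactors = FALSE)
  else jsonlite::fromJSON(path)
}

#' Generate one fixture file per supported format
#'
#' Writes a small correlated closed-shell occupancy set as molden, wfx,
#' plain and JSON files, a spin-resolved molden file, a sampled amplitude
#' container, and a threshold-table JSON into `dir`.
#'
#' @param dir output directory (created if missing).
#' @param seed seed for the amplitude fixture.
#' @return Named character vector of the paths written.
#' @export
write_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cs <- closed_shell_occupancies(c(1.97, 1.91, 0.08, 0.04),
                                 label = "synthetic correlated fixture")
  sp <- spin_occupancy_set(c(0.99, 0.93, 0.05, 0.03),
                           c(0.98, 0.94, 0.06, 0.02),
                           label = "synthetic open-shell fixture")
  paths <- c(
    molden = write_molden_occupancies(cs, file.path(dir, "closed_shell.molden")),
    molden_spin = write_molden_occupancies(sp, file.path(dir, "open_shell.molden")),
    wfx = write_wfx_occupancies(cs, file.path(dir, "closed_shell.wfx")),
    plain = write_plain_occupancies(cs, file.path(dir, "closed_shell.txt")),
    json = write_json_occupancies(cs, file.path(dir, "closed_shell.json")),
    amplitudes = write_amplitudes(sample_amplitudes(2, 3, 0.08, seed),
                                  file.path(dir, "amplitudes.t2.json")))
  tt <- default_thresholds()
  jsonlite::write_json(as.list(tt), file.path(dir, "thresholds.json"),
                       digits = I(17))
  c(paths, thresholds = file.path(dir, "thresholds.json"))
}
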