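#' Define an analyte panel
#'
#' A panel describes the compounds an assay quantifies: their short codes,
#' full names, compound class (sugar-bound glycoside or sugar-free aglycone),
#' and which one serves as the internal standard for single-marker
#' quantification. Stock concentrations (mg/mL of the mixed standard
#' solution) and nominal retention times (min) ride along because the
#' dilution ladder and peak assignment both need them.
#'
#' @param code Character vector of unique short analyte codes.
#' @param name Full compound names, same length as `code`.
#' @param compound_class `"glycoside"` or `"aglycone"` per analyte.
#' @param internal_standard Code of the single analyte used as internal
#'   standard; must appear in `code`.
#' @param stock_mg_ml Stock concentration of the mixed standard solution in
#'   mg/mL per analyte (optional, `NA` allowed).
#' @param rt_min Nominal retention time in minutes per analyte (optional).
#'
#' @return A data frame of class `analyte_panel` with one row per analyte
#'   and a logical `internal_standard` column.
#' @seealso [default_panel()] for the six-chromone panel.
#' @export
analyte_panel <- function(code, name = code,
                          compound_class,
                          internal_standard,
                          stock_mg_ml = NA_real_,
                          rt_min = NA_real_) {
  code <- as.character(code)
  if (anyDuplicated(code)) {
    stop("analyte codes must be unique within a panel", call. = FALSE)
  }
  if (!all(compound_class %in% c("glycoside", "aglycone"))) {
    stop("compound_class must be 'glycoside' or 'aglycone'", call. = FALSE)
  }
  if (length(internal_standard) != 1L || !internal_standard %in% code) {
    stop("exactly one internal standard, drawn from the panel codes, is required",
         call. = FALSE)
  }
  panel <- data.frame(
    code = code,
    name = rep_len(as.character(name), length(code)),
    compound_class = rep_len(compound_class, length(code)),
    internal_standard = code == internal_standard,
    stock_mg_ml = rep_len(as.numeric(stock_mg_ml), length(code)),
    rt_min = rep_len(as.numeric(rt_min), length(code)),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("analyte_panel", "data.frame")
  panel
}

#' The six-chromone panel of Saposhnikoviae Radix
#'
#' Three chromone glycosides (GC, GV, GH) and their aglycones (C, V, H),
#' with GV as the internal standard. Stock concentrations are those of the
#' mixed standard solution; retention times are nominal values consistent
#' with the elution order GC < C < GV < V < GH < H on a C18 gradient and
#' are used as defaults by the peak-assignment and simulation helpers.
#'
#' @return An [analyte_panel()] with six rows.
#' @export
#' @examples
#' default_panel()
default_panel <- function() {
  analyte_panel(
    code = c("GC", "C", "GV", "V", "GH", "H"),
    name = c("prim-O-glucosylcimifugin", "cimifugin",
             "4'-O-beta-D-glucosyl-5-O-methylvisamminol",
             "5-O-methylvisamminol", "sec-O-glucosylhamaudol", "hamaudol"),
    compound_class = c("glycoside", "aglycone", "glycoside",
                       "aglycone", "glycoside", "aglycone"),
    internal_standard = "GV",
    stock_mg_ml = c(0.2096, 0.1220, 0.3340, 0.0808, 0.1636, 0.0369),
    rt_min = c(10.5, 16.2, 20.8, 27.5, 35.4, 43.9)
  )
}

#' @export
print.analyte_panel <- function(x, ...) {
  is_code <- x$code[x$internal_standard]
  cat(sprintf("Analyte panel: %d compounds (internal standard: %s)\n",
              nrow(x), is_code))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Internal standard code of a panel
#' @param panel An [analyte_panel()].
#' @return The internal standard's code.
#' @export
internal_standard <- function(panel) {
  stopifnot(inherits(panel, "analyte_panel"))
  panel$code[panel$internal_standard]
}

# shared argument checks -------------------------------------------------

check_scalar_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("%s must be a single positive number", what), call. = FALSE)
  }
  invisible(x)
}
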