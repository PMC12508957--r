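#' Construct a formulation
#'
#' @param form dosage form: `"iv_bolus"`, `"oral_suspension"`, `"oral_tablet"`
#'   or `"oral_solution"`.
#' @param dose dose in mg (> 0).
#' @param psd a [psd()] for oral solid/suspension forms; `NULL` for i.v. bolus
#'   and oral solution.
#' @param nano_effect enable the nano solubility effect (see
#'   [nano_solubility_factor()]).
#' @return object of class `formulation`.
#' @export
formulation <- function(form = c("iv_bolus", "oral_suspension", "oral_tablet",
                                 "oral_solution"),
                        dose, psd = NULL, nano_effect = FALSE) {
  form <- match.arg(form)
  check_number(dose, "dose", 0, strict_lower = TRUE)
  needs_psd <- form %in% c("oral_suspension", "oral_tablet")
  if (needs_psd && !inherits(psd, "psd"))
    stopf("a psd is required for dosage form '%s'", form)
  if (!needs_psd) psd <- NULL
  structure(list(form = form, dose = dose, psd = psd,
                 nano_effect = isTRUE(nano_effect)),
            class = "formulation")
}

#' @export
print.formulation <- function(x, ...) {
  cat(sprintf("<formulation> %s, %.4g mg%s%s\n", x$form, x$dose,
              if (!is.null(x$psd)) sprintf(", %d-bin PSD", x$psd$n_bins) else "",
              if (x$nano_effect) ", nano effect on" else ""))
  invisible(x)
}
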