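#' @include io.R
NULL

#' Per-sample consumables rates
#'
#' Default rates for the three viability assays: the classical drop
#' assay uses 15 pipette tips per sample (one per dilution/transfer);
#' the embedded-cone assay uses a single tip and 200 uL of 0.5% gel; a
#' spiral plater uses no tips but one Petri dish per sample, poured with
#' 25 mL of 1.5% agar. Dish amortisation for the drop assay (samples
#' sharing an agar pad) varies by lab and has no default — set
#' `dishesPerSample["drop_cfu"]` to use it.
#'
#' @param ... Named overrides of the default rates.
#' @return A list of rates used by [consumablesEstimate()] and
#'   [savingsRatio()].
#' @export
consumablesModel <- function(...) {
  model <- list(
    tipsPerSample = c(drop_cfu = 15, spiral_plater = 0, gva = 1),
    dishesPerSample = c(drop_cfu = NA_real_, spiral_plater = 1, gva = 0),
    tipsPerBox = 96,
    agarPerDishMl = 25, agarConcDish = 0.015,   # 1.5% w/v
    gelPerSampleUl = 200, gelConcGva = 0.005)   # 0.5% w/v
  utils::modifyList(model, list(...))
}

#' Consumables needed for a batch of samples
#'
#' Tips, tip boxes (ceiling of tips / box size), Petri dishes and agar
#' mass (grams of agar powder) for `nSamples` measurements by the chosen
#' method. A 2,267-sample screen needs 355 tip boxes by the drop assay,
#' 2,267 dishes by spiral plating, and 24 tip boxes by the embedded-cone
#' assay.
#'
#' @param nSamples Number of samples (>= 1).
#' @param method `"drop_cfu"`, `"spiral_plater"` or `"gva"`.
#' @param model Rates from [consumablesModel()].
#' @return List: `tips`, `tipBoxes`, `petriDishes`, `agarGrams`.
#' @examples
#' consumablesEstimate(2267, "gva")$tipBoxes     # 24
#' consumablesEstimate(2267, "drop_cfu")$tipBoxes # 355
#' @export
consumablesEstimate <- function(nSamples, method = c("drop_cfu",
                                "spiral_plater", "gva"),
                                model = consumablesModel()) {
  method <- match.arg(method)
  stopifnot(nSamples >= 1)
  tips <- nSamples * model$tipsPerSample[[method]]
  dishes <- nSamples * model$dishesPerSample[[method]]
  agar <- if (method == "gva")
    nSamples * model$gelPerSampleUl / 1000 * model$gelConcGva
  else
    dishes * model$agarPerDishMl * model$agarConcDish
  list(tips = tips, tipBoxes = ceiling(tips / model$tipsPerBox),
       petriDishes = dishes, agarGrams = agar)
}

#' Per-sample consumption ratio between two methods
#'
#' How many times more of a resource method A uses than method B, on the
#' per-sample rates: the drop assay uses 15x the tips of the
#' embedded-cone assay.
#'
#' @param methodA,methodB Method names as in [consumablesEstimate()].
#' @param resource `"tips"` or `"dishes"`.
#' @param model Rates from [consumablesModel()].
#' @return The ratio (a single number).
#' @examples
#' savingsRatio("drop_cfu", "gva", "tips")  # 15
#' @export
savingsRatio <- function(methodA, methodB, resource = c("tips", "dishes"),
                         model = consumablesModel()) {
  resource <- match.arg(resource)
  rates <- switch(resource, tips = model$tipsPerSample,
                  dishes = model$dishesPerSample)
  for (m in c(methodA, methodB))
    if (!m %in% names(rates)) stop("unknown method '", m, "'")
  a <- rates[[methodA]]; b <- rates[[methodB]]
  if (is.na(a) || is.na(b))
    stop("no configured ", resource, " rate for one of the methods")
  if (b == 0)
    stop("method '", methodB, "' consumes no ", resource,
         ": ratio undefined")
  a / b
}
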