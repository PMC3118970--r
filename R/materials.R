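#' Linear elastic material properties of the spine model
#'
#' Published linear material properties used throughout the model: cortical
#' and cancellous vertebral bone, the three growth-plate layers (sensitive,
#' newly formed bone, transition) and the two disc constituents (nucleus
#' pulposus, annulus fibrosus).
#'
#' @return A tibble with columns `component`, `tissue`, `young_modulus`
#'   (MPa) and `poisson_ratio`.
#' @export
#' @examples
#' material_table()
material_table <- function() {
  tibble::tibble(
    component = c("vertebral_body", "vertebral_body",
                  "growth_plate", "growth_plate", "growth_plate",
                  "disc", "disc"),
    tissue = c("cortical", "cancellous",
               "sensitive", "newly_formed_bone", "transition",
               "nucleus", "annulus"),
    young_modulus = c(14500, 400, 12, 100, 300, 2, 8),
    poisson_ratio = c(0.3, 0.3, 0.4, 0.3, 0.3, 0.49, 0.45)
  )
}

#' Look up the Young's modulus of a model tissue
#'
#' @param tissue Tissue name as listed in [material_table()].
#' @return Young's modulus in MPa.
#' @export
young_modulus <- function(tissue) {
  tab <- material_table()
  i <- match(tissue, tab$tissue)
  if (anyNA(i)) abort(paste0("unknown tissue: ", paste(tissue[is.na(i)], collapse = ", ")))
  tab$young_modulus[i]
}
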