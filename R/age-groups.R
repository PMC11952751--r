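#' Lifespan age groups
#'
#' The seven age groups partition \[0, Inf): infant < 1 y, early childhood
#' 1-6 y, late childhood 7-12 y, adolescence 13-19 y, young adulthood
#' 20-39 y, middle adulthood 40-59 y, late adulthood >= 60 y. Integer
#' boundary ages belong to the group whose range starts there (1 y is early
#' childhood, 7 y late childhood, and so on).
#'
#' @return `age_group_levels()`: the ordered group labels.
#' @export
age_group_levels <- function() {
  c("infant", "early_childhood", "late_childhood", "adolescence",
    "young_adulthood", "middle_adulthood", "late_adulthood")
}

#' @rdname age_group_levels
#' @param age Numeric vector of ages in years (fractional allowed, >= 0).
#' @return `assign_age_group()`: factor with the seven ordered levels.
#' @examples
#' assign_age_group(c(0.9, 13, 60))
#' @export
assign_age_group <- function(age) {
  age <- as.numeric(age)
  if (any(age < 0, na.rm = TRUE)) stop("age must be >= 0")
  cut(age, breaks = c(0, 1, 7, 13, 20, 40, 60, Inf), right = FALSE,
      labels = age_group_levels())
}
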