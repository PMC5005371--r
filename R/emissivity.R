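#' Estimate an apparent emission coefficient from paired temperatures
#'
#' Cameras are commonly operated with the emission coefficient set to 1 and
#' the recorded temperatures corrected afterwards. The apparent emission
#' coefficient of a surface is estimated as the quotient of the contact
#' (thermocouple) temperature and the image-derived temperature, evaluated
#' on the kelvin scale — the only scale on which a temperature ratio is
#' meaningful:
#' \deqn{\epsilon = (T_{contact} + 273.15) / (T_{image} + 273.15)}
#' Because no background (reflected) temperature is compensated, this is an
#' apparent emissivity. Values outside (0.5, 1.2] are physically suspect
#' and trigger a warning.
#'
#' @param t_contact contact thermocouple temperature, degrees Celsius.
#' @param t_image image-derived temperature of the same surface, degrees
#'   Celsius (acquired with the camera emissivity at 1).
#' @return dimensionless emission coefficient.
#' @export
#' @examples
#' estimate_emissivity(30, 33)   # 303.15/306.15 = 0.9902
estimate_emissivity <- function(t_contact, t_image) {
  if (any(!is.finite(t_contact)) || any(!is.finite(t_image)))
    stop("non-finite temperature input")
  if (any(t_contact < -273.15) || any(t_image <= -273.15))
    stop("temperature below absolute zero")
  eps <- (t_contact + 273.15) / (t_image + 273.15)
  if (any(eps <= 0.5 | eps > 1.2))
    warning("estimated emissivity outside (0.5, 1.2]: suspect calibration pair")
  eps
}

#' Correct apparent temperatures by an emission coefficient
#'
#' Inverts the acquisition-at-emissivity-1 convention: the corrected kelvin
#' temperature is the apparent kelvin temperature multiplied by the
#' emission coefficient, so that correcting an image temperature with the
#' coefficient estimated by [estimate_emissivity()] recovers the contact
#' temperature exactly. The map is monotone increasing in the apparent
#' temperature and the identity at emissivity 1.
#'
#' @param x apparent temperature(s), degrees Celsius; scalar, vector or
#'   matrix.
#' @param emissivity emission coefficient in (0, 1.2].
#' @return corrected temperature(s), degrees Celsius, same shape as `x`.
#' @export
correct_emissivity <- function(x, emissivity) {
  if (!is.numeric(emissivity) || length(emissivity) != 1 ||
      !is.finite(emissivity) || emissivity <= 0)
    stop("emissivity must be a single positive number")
  if (any(!is.finite(x))) stop("non-finite temperature input")
  (x + 273.15) * emissivity - 273.15
}
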