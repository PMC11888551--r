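#' Model family table
#'
#' The six architecture variants are fully determined by four attributes:
#' the kernel size `k` of the two beta convolutional processing blocks, the
#' readout mode (`FCL` = dense over all hypercolumns, `CTL` = dense over the
#' center hypercolumn only), whether a single-headed spatial self-attention
#' (SA) layer is inserted between the alpha and beta stacks, and the SA value
#' flag `gamma` (`TRUE` = the value vector is linearly transformed, allowing
#' channel mixing; `FALSE` = values are the raw features, so attention is a
#' purely spatial reweighting).
#'
#' @format A data frame with one row per family.
#' @keywords internal
family_table <- function() {
  data.frame(
    family = c("ff", "ff_sa", "rf", "rf_sa", "rf_sa_star", "ff_sa_star"),
    beta_kernel_k = c(3L, 3L, 1L, 1L, 1L, 1L),
    readout = c("FCL", "FCL", "CTL", "CTL", "CTL", "FCL"),
    sa_present = c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE),
    sa_gamma = c(NA, TRUE, NA, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Declare a model architecture
#'
#' Constructs a declarative architecture description from which any model
#' variant is assembled. The family name fixes the beta kernel size, readout
#' mode and self-attention configuration; passing an explicit value that
#' contradicts the family is an error (this guards against silently running
#' a model other than the one named).
#'
#' @param family One of `"ff"`, `"ff_sa"`, `"rf"`, `"rf_sa"`, `"rf_sa_star"`,
#'   `"ff_sa_star"`.
#' @param channels_c Number of channels, constant through the whole trunk.
#' @param input_side Input image side in pixels (square input, default 50).
#' @param beta_kernel_k,readout,sa_present,sa_gamma Optional; if supplied they
#'   must agree with the family.
#' @return An object of class `sacnn_spec`.
#' @examples
#' model_spec("rf", channels_c = 8)
#' @export
model_spec <- function(family, channels_c, input_side = 50L,
                       beta_kernel_k = NULL, readout = NULL,
                       sa_present = NULL, sa_gamma = NULL) {
  tab <- family_table()
  if (!family %in% tab$family)
    stop("unknown family '", family, "'", call. = FALSE)
  row <- tab[tab$family == family, ]
  check_field <- function(value, expected, name) {
    if (!is.null(value)) {
      same <- if (is.na(expected)) is.na(value) else
        isTRUE(value == expected) && !is.na(value)
      if (!same)
        stop("field '", name, "' = ", value, " contradicts family '", family,
             "' (expects ", expected, ")", call. = FALSE)
    }
    expected
  }
  channels_c <- as.integer(channels_c)
  input_side <- as.integer(input_side)
  if (length(channels_c) != 1 || is.na(channels_c) || channels_c < 1)
    stop("field 'channels_c' must be a positive integer", call. = FALSE)
  if (length(input_side) != 1 || is.na(input_side) || input_side < 16)
    stop("field 'input_side' must be an integer >= 16 (the valid-conv/pool ",
         "chain needs at least a 16-pixel side)", call. = FALSE)
  spec <- structure(list(
    family = family,
    channels_c = channels_c,
    beta_kernel_k = check_field(beta_kernel_k, row$beta_kernel_k,
                                "beta_kernel_k"),
    readout = check_field(readout, row$readout, "readout"),
    sa_present = check_field(sa_present, row$sa_present, "sa_present"),
    sa_gamma = check_field(sa_gamma, row$sa_gamma, "sa_gamma"),
    input_side = input_side
  ), class = "sacnn_spec")
  spec
}

#' @export
print.sacnn_spec <- function(x, ...) {
  cat("<sacnn_spec> family=", x$family, " c=", x$channels_c,
      " k=", x$beta_kernel_k, " readout=", x$readout,
      " sa=", x$sa_present,
      if (isTRUE(x$sa_present)) paste0(" (gamma=", x$sa_gamma, ")") else "",
      " input=", x$input_side, "x", x$input_side, "\n", sep = "")
  invisible(x)
}

#' Spatial side of the alpha-stack feature map
#'
#' Two stages of (valid 5x5 convolution, 2x2 max pooling with stride 2 and
#' floor division) map an `H`-pixel side to
#' `floor((floor((H - 4) / 2) - 4) / 2)`; a 50-pixel input yields a 9x9 map.
#'
#' @param input_side Input side in pixels.
#' @return Integer spatial side after the alpha stack.
#' @export
alpha_output_side <- function(input_side) {
  s <- (((input_side - 4) %/% 2) - 4) %/% 2
  as.integer(s)
}

# Spatial side at the readout (after the beta convolutions).
readout_side <- function(spec) {
  s <- alpha_output_side(spec$input_side)
  s <- s - 2L * (spec$beta_kernel_k %/% 2L) * 2L  # two beta blocks
  if (s < 1) stop("input_side too small for the valid-convolution chain",
                  call. = FALSE)
  as.integer(s)
}

#' Serialize / deserialize a model spec as YAML
#'
#' @param spec A `sacnn_spec`.
#' @param path File path.
#' @return `read_model_spec` returns a `sacnn_spec`.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "sacnn_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- yaml::read_yaml(path)
  model_spec(x$family, x$channels_c, x$input_side,
             beta_kernel_k = x$beta_kernel_k, readout = x$readout,
             sa_present = x$sa_present,
             sa_gamma = if (is.null(x$sa_gamma)) NULL else x$sa_gamma)
}
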