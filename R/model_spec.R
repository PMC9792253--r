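#' Declarative 1D-MobileNet architecture specification
#'
#' A model spec is an ordered table of macro-layers (initial convolution,
#' inverted-residual bottleneck stages, final pointwise convolution, global
#' average pooling, linear classifier head) with the MobileNet stage
#' parameters: expansion factor `t`, output channels `c`, repetitions `n`
#' and stride `s`.
#'
#' @param layers data frame with columns `operator` (one of `"conv1d"`,
#'   `"bottleneck"`, `"pointwise_conv"`, `"avgpool"`, `"linear"`), `t`,
#'   `c`, `n`, `s`, `kernel`.
#' @param input_length input window length in samples.
#' @param input_channels number of input channels (1 for per-channel EEG
#'   windows).
#' @param num_classes number of output classes.
#' @return an object of class `model_spec`.
#' @seealso [default_spec()], [shape_flow()], [build_model()]
#' @export
model_spec <- function(layers, input_length = 1024L, input_channels = 1L,
                       num_classes = 2L) {
  need <- c("operator", "t", "c", "n", "s", "kernel")
  assert_that(all(need %in% names(layers)), "layers is missing columns")
  ops <- c("conv1d", "bottleneck", "pointwise_conv", "avgpool", "linear")
  assert_that(all(layers$operator %in% ops), "unknown operator in layers")
  conv_rows <- layers$operator %in% c("conv1d", "bottleneck", "pointwise_conv")
  assert_that(all(layers$t[layers$operator == "bottleneck"] >= 1),
              "expansion factor t must be >= 1")
  assert_that(all(layers$c[conv_rows] >= 1), "output channels must be >= 1")
  assert_that(all(layers$n[conv_rows] >= 1), "repetitions must be >= 1")
  assert_that(all(layers$s[conv_rows] %in% c(1, 2)), "stride must be 1 or 2")
  assert_that(all(layers$kernel[conv_rows] %% 2 == 1), "kernels must be odd")
  structure(list(layers = layers,
                 input_length = as.integer(input_length),
                 input_channels = as.integer(input_channels),
                 num_classes = as.integer(num_classes)),
            class = "model_spec")
}

spec_row <- function(operator, t = NA, c = NA, n = 1L, s = 1L, kernel = 1L) {
  data.frame(operator = operator, t = t, c = c, n = n, s = s, kernel = kernel)
}

#' The reference 11-row 1D-MobileNet specification
#'
#' Returns the architecture used for seizure-window classification: a
#' stride-2 initial convolution (1 to 32 channels, kernel 3), seven
#' inverted-residual bottleneck stages with `(t, c, n, s)` =
#' (1,16,1,1), (6,24,2,2), (6,32,3,2), (6,64,4,2), (6,96,3,1),
#' (6,160,3,2), (6,320,1,1), a pointwise convolution to 1280 channels,
#' global average pooling, and a 2-class linear head. For a 1024-sample
#' single-channel window the shape flow is
#' 1024x1 -> 512x32 -> 512x16 -> 256x24 -> 128x32 -> 64x64 -> 64x96 ->
#' 32x160 -> 32x320 -> 32x1280 -> 1x1280 -> 2.
#'
#' @param input_length input window length (samples), default 1024.
#' @return a [model_spec()].
#' @examples
#' spec <- default_spec()
#' shape_flow(spec)
#' @export
default_spec <- function(input_length = 1024L) {
  layers <- rbind(
    spec_row("conv1d", c = 32, s = 2L, kernel = 3L),
    spec_row("bottleneck", t = 1, c = 16, n = 1L, s = 1L, kernel = 3L),
    spec_row("bottleneck", t = 6, c = 24, n = 2L, s = 2L, kernel = 3L),
    spec_row("bottleneck", t = 6, c = 32, n = 3L, s = 2L, kernel = 3L),
    spec_row("bottleneck", t = 6, c = 64, n = 4L, s = 2L, kernel = 3L),
    spec_row("bottleneck", t = 6, c = 96, n = 3L, s = 1L, kernel = 3L),
    spec_row("bottleneck", t = 6, c = 160, n = 3L, s = 2L, kernel = 3L),
    spec_row("bottleneck", t = 6, c = 320, n = 1L, s = 1L, kernel = 3L),
    spec_row("pointwise_conv", c = 1280, s = 1L, kernel = 1L),
    spec_row("avgpool"),
    spec_row("linear", c = 2)
  )
  model_spec(layers, input_length = input_length, input_channels = 1L,
             num_classes = 2L)
}

conv_out_len <- function(len, kernel, stride) {
  pad <- (kernel - 1L) %/% 2L
  as.integer(floor((len + 2L * pad - kernel) / stride) + 1L)
}

#' Simulate the shape flow of a model specification
#'
#' Walks the macro-layer table and reports the input length and channel
#' count entering each row, mirroring the "Input" column of the
#' architecture table.
#'
#' @param spec a [model_spec()].
#' @return data frame with columns `operator`, `in_length`, `in_channels`,
#'   `out_length`, `out_channels`.
#' @export
shape_flow <- function(spec) {
  assert_that(inherits(spec, "model_spec"), "spec must be a model_spec")
  len <- spec$input_length
  ch <- spec$input_channels
  rows <- lapply(seq_len(nrow(spec$layers)), function(i) {
    l <- spec$layers[i, ]
    in_len <- len; in_ch <- ch
    if (l$operator %in% c("conv1d", "pointwise_conv")) {
      len <<- conv_out_len(len, l$kernel, l$s)
      ch <<- l$c
    } else if (l$operator == "bottleneck") {
      # only the first repetition strides
      len <<- conv_out_len(len, l$kernel, l$s)
      ch <<- l$c
    } else if (l$operator == "avgpool") {
      len <<- 1L
    } else if (l$operator == "linear") {
      ch <<- spec$num_classes
    }
    data.frame(operator = l$operator, in_length = in_len, in_channels = in_ch,
               out_length = len, out_channels = ch)
  })
  do.call(rbind, rows)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %d macro-layers, input %dx%d, %d classes\n",
              nrow(x$layers), x$input_length, x$input_channels, x$num_classes))
  print(cbind(x$layers, shape_flow(x)[c("in_length", "in_channels")]))
  invisible(x)
}

#' Serialize a model specification to / from JSON
#'
#' @param spec a [model_spec()].
#' @param path file path.
#' @return `write_model_spec()` returns `path` invisibly;
#'   `read_model_spec()` returns a [model_spec()].
#' @export
write_model_spec <- function(spec, path) {
  assert_that(inherits(spec, "model_spec"), "spec must be a model_spec")
  jsonlite::write_json(
    list(layers = spec$layers, input_length = spec$input_length,
         input_channels = spec$input_channels, num_classes = spec$num_classes),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- as.data.frame(obj$layers)
  model_spec(layers, obj$input_length, obj$input_channels, obj$num_classes)
}
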