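# Instantiation of a model_spec into a flat graph of atomic ops with
# analytic parameter and multiply-add accounting.
#
# Accounting conventions (the ones used for "Parameters (M)" and
# "Mult-adds (M)" tables):
#   * convolutions are bias-free (batch normalization supplies the shift);
#     parameters = kernel * in_channels/groups * out_channels
#   * batch normalization contributes 2 * channels learnable scalars
#   * the linear head has a bias: in * out + out
#   * MACs: conv = kernel * (in_channels/groups) * out_channels * out_length,
#     linear = in * out; normalization, activation and pooling are excluded.

new_op <- function(kind, name, in_ch = NA_integer_, out_ch = NA_integer_,
                   kernel = NA_integer_, stride = NA_integer_,
                   groups = NA_integer_, in_len = NA_integer_,
                   out_len = NA_integer_) {
  list(kind = kind, name = name, in_ch = in_ch, out_ch = out_ch,
       kernel = kernel, stride = stride, groups = groups,
       in_len = in_len, out_len = out_len)
}

op_params <- function(op) {
  switch(op$kind,
    conv = op$kernel * (op$in_ch %/% op$groups) * op$out_ch,
    bn = 2L * op$out_ch,
    linear = op$in_ch * op$out_ch + op$out_ch,
    0L)
}

op_macs <- function(op) {
  switch(op$kind,
    conv = as.double(op$kernel) * (op$in_ch %/% op$groups) * op$out_ch * op$out_len,
    linear = as.double(op$in_ch) * op$out_ch,
    0)
}

#' Instantiate a model graph from a specification
#'
#' Expands the macro-layer table into atomic operations. Each bottleneck
#' repetition becomes: pointwise expansion convolution (omitted when the
#' expansion factor is 1) + batch norm + clipped-linear (ReLU6) activation,
#' depthwise convolution (stride `s` in the first repetition of a stage,
#' 1 afterwards) + batch norm + activation, then pointwise projection +
#' batch norm with no activation. A residual (skip) addition is inserted
#' when the stride is 1 and input and output channel counts match.
#'
#' @param spec a [model_spec()].
#' @return a `model_graph`: list with `ops` (atomic op list), `layers`
#'   (accounting data frame with per-op parameter and MAC counts), `spec`,
#'   and totals `n_params` / `n_macs`.
#' @examples
#' g <- build_model(default_spec())
#' count_parameters(g)
#' count_mult_adds(g)
#' @export
build_model <- function(spec) {
  assert_that(inherits(spec, "model_spec"), "spec must be a model_spec")
  ops <- list()
  len <- spec$input_length
  ch <- spec$input_channels
  push <- function(op) ops[[length(ops) + 1L]] <<- op

  for (i in seq_len(nrow(spec$layers))) {
    l <- spec$layers[i, ]
    if (l$operator %in% c("conv1d", "pointwise_conv")) {
      out_len <- conv_out_len(len, l$kernel, l$s)
      nm <- sprintf("%s_%d", l$operator, i)
      push(new_op("conv", nm, ch, l$c, l$kernel, l$s, 1L, len, out_len))
      push(new_op("bn", paste0(nm, "_bn"), l$c, l$c, out_len = out_len))
      push(new_op("relu6", paste0(nm, "_relu"), l$c, l$c, out_len = out_len))
      len <- out_len; ch <- l$c
    } else if (l$operator == "bottleneck") {
      for (rep_i in seq_len(l$n)) {
        stride <- if (rep_i == 1L) l$s else 1L
        in_ch <- ch
        out_ch <- l$c
        hidden <- as.integer(in_ch * l$t)
        out_len <- conv_out_len(len, l$kernel, stride)
        residual <- stride == 1L && in_ch == out_ch
        nm <- sprintf("bottleneck_%d_%d", i, rep_i)
        if (residual) push(new_op("res_save", paste0(nm, "_skip"),
                                  in_ch, in_ch, out_len = len))
        if (l$t != 1) {
          push(new_op("conv", paste0(nm, "_expand"), in_ch, hidden, 1L, 1L, 1L,
                      len, len))
          push(new_op("bn", paste0(nm, "_expand_bn"), hidden, hidden,
                      out_len = len))
          push(new_op("relu6", paste0(nm, "_expand_relu"), hidden, hidden,
                      out_len = len))
        }
        push(new_op("conv", paste0(nm, "_dw"), hidden, hidden, l$kernel,
                    stride, hidden, len, out_len))
        push(new_op("bn", paste0(nm, "_dw_bn"), hidden, hidden,
                    out_len = out_len))
        push(new_op("relu6", paste0(nm, "_dw_relu"), hidden, hidden,
                    out_len = out_len))
        push(new_op("conv", paste0(nm, "_project"), hidden, out_ch, 1L, 1L, 1L,
                    out_len, out_len))
        push(new_op("bn", paste0(nm, "_project_bn"), out_ch, out_ch,
                    out_len = out_len))
        if (residual) push(new_op("res_add", paste0(nm, "_add"),
                                  out_ch, out_ch, out_len = out_len))
        len <- out_len; ch <- out_ch
      }
    } else if (l$operator == "avgpool") {
      push(new_op("avgpool", sprintf("avgpool_%d", i), ch, ch,
                  in_len = len, out_len = 1L))
      len <- 1L
    } else if (l$operator == "linear") {
      push(new_op("linear", sprintf("linear_%d", i), ch, spec$num_classes,
                  in_len = 1L, out_len = 1L))
      ch <- spec$num_classes
    }
  }

  layers <- data.frame(
    name = vapply(ops, `[[`, "", "name"),
    kind = vapply(ops, `[[`, "", "kind"),
    in_channels = vapply(ops, function(o) as.integer(o$in_ch), 1L),
    out_channels = vapply(ops, function(o) as.integer(o$out_ch), 1L),
    out_length = vapply(ops, function(o) as.integer(o$out_len), 1L),
    params = vapply(ops, function(o) as.double(op_params(o)), 1),
    macs = vapply(ops, function(o) op_macs(o), 1)
  )
  structure(list(ops = ops, layers = layers, spec = spec,
                 n_params = sum(layers$params), n_macs = sum(layers$macs)),
            class = "model_graph")
}

#' Total trainable parameter count of a model graph
#'
#' Sums convolution weights, batch-normalization scale/shift pairs and the
#' linear head's weights and bias over all layers.
#'
#' @param graph a `model_graph` from [build_model()].
#' @return integer-valued total.
#' @export
count_parameters <- function(graph) {
  assert_that(inherits(graph, "model_graph"), "graph must be a model_graph")
  graph$n_params
}

#' Total multiply-add count of a model graph
#'
#' Counts multiply-accumulate operations of convolutional and linear layers
#' for one forward pass at the given input length (normalization,
#' activation and pooling excluded — the dominant convention for mult-add
#' tables). Parameters are length-invariant; MACs are not, so the graph is
#' re-simulated when `input_length` differs from the spec.
#'
#' @param graph a `model_graph`.
#' @param input_length input window length in samples.
#' @return total MAC count (double).
#' @export
count_mult_adds <- function(graph, input_length = NULL) {
  assert_that(inherits(graph, "model_graph"), "graph must be a model_graph")
  if (!is.null(input_length) && input_length != graph$spec$input_length) {
    spec <- graph$spec
    spec$input_length <- as.integer(input_length)
    graph <- build_model(spec)
  }
  graph$n_macs
}

#' @export
print.model_graph <- function(x, ...) {
  cat(sprintf("<model_graph> %d atomic ops | %.0f parameters (%.1f M) | %.0f MACs (%.1f M at length %d)\n",
              length(x$ops), x$n_params, x$n_params / 1e6,
              x$n_macs, x$n_macs / 1e6, x$spec$input_length))
  invisible(x)
}

#' Per-layer summary table of a model graph
#'
#' The architecture-table analogue: one row per parameterised or
#' shape-changing op with output shape, parameter count and MACs.
#'
#' @param object a `model_graph`.
#' @param ... unused.
#' @return the accounting data frame, invisibly; printed as a table.
#' @export
summary.model_graph <- function(object, ...) {
  tab <- object$layers
  keep <- tab$kind %in% c("conv", "bn", "linear", "avgpool")
  tab <- tab[keep, c("name", "kind", "out_length", "out_channels",
                     "params", "macs")]
  cat(sprintf("%-28s %-8s %9s %9s %12s %14s\n",
              "layer", "kind", "out_len", "out_ch", "params", "mult_adds"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("%-28s %-8s %9d %9d %12.0f %14.0f\n",
                tab$name[i], tab$kind[i], tab$out_length[i],
                tab$out_channels[i], tab$params[i], tab$macs[i]))
  }
  cat(sprintf("%-28s %-8s %9s %9s %12.0f %14.0f\n", "TOTAL", "", "", "",
              object$n_params, object$n_macs))
  invisible(tab)
}
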