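# Shared layer constructors for the network modules.

conv_layer <- function(k, cin, cout, groups = 1L, zero_init = FALSE) {
  w <- if (zero_init) {
    nn_param(array(0, dim = c(k, k, cin %/% groups, cout)))
  } else {
    init_conv_w(k, cin %/% groups, cout)
  }
  list(w = w, b = nn_param(rep(0, cout)), pad = (k - 1L) %/% 2L,
       groups = as.integer(groups))
}

conv_apply <- function(ly, x) nn_conv2d(x, ly$w, ly$b, ly$pad, ly$groups)

# conv + batch norm + ReLU
cbr_layer <- function(k, cin, cout, groups = 1L) {
  list(conv = conv_layer(k, cin, cout, groups), bn = bn_new(cout))
}

cbr_apply <- function(ly, x, training) {
  nn_relu(nn_bn(conv_apply(ly$conv, x), ly$bn, training))
}

# plain U-Net stage: two 3x3 conv + BN + ReLU layers
double_conv_layer <- function(cin, cout) {
  list(a = cbr_layer(3L, cin, cout), b = cbr_layer(3L, cout, cout))
}

double_conv_apply <- function(ly, x, training) {
  cbr_apply(ly$b, cbr_apply(ly$a, x, training), training)
}

#' Count trainable scalars in a model or block
#' @param x any nested structure containing parameters
#' @return integer number of trainable scalar weights
#' @export
count_params <- function(x) {
  sum(vapply(collect_params(x), function(p) length(p$v), 0))
}
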