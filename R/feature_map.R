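#' Feature maps
#'
#' A feature map is the currency passed between every layer of the network: a
#' dense `C x H x W` array of real activations (channel index fastest). Plain
#' numeric arrays with three dimensions are accepted everywhere; these helpers
#' construct and validate them.
#'
#' @param values numeric vector or array of activations, recycled into shape.
#' @param channels,height,width positive integer extents.
#' @return A `C x H x W` numeric array.
#' @examples
#' x <- feature_map(0, channels = 3, height = 8, width = 8)
#' dim(x)
#' @export
feature_map <- function(values, channels, height, width) {
  stopifnot(channels >= 1, height >= 1, width >= 1)
  x <- array(as.numeric(values), dim = c(channels, height, width))
  check_feature_map(x)
  x
}

#' @rdname feature_map
#' @param x object to validate.
#' @export
check_feature_map <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("a feature map must be a 3-d array laid out (channels, height, width)",
         call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("feature map contains non-finite values", call. = FALSE)
  }
  invisible(x)
}

# internal: promote a single map (C,H,W) to a batch (C,H,W,1)
as_batch <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

# internal: drop a singleton batch axis back to (C,H,W)
drop_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 4L && d[4] == 1L) dim(x) <- d[1:3]
  x
}

# internal: stack a list of (C,H,W) arrays into (C,H,W,B)
stack_batch <- function(maps) {
  d <- dim(maps[[1]])
  out <- array(0, c(d, length(maps)))
  for (i in seq_along(maps)) out[, , , i] <- maps[[i]]
  out
}
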