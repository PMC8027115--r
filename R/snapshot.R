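#' Save and restore model snapshots
#'
#' Serializes an [msom()] or [feasibility_net()] (weights, parameters, step
#' counter) to a plain JSON container, so trained models can be archived or
#' moved between sessions without binary formats.  `read_snapshot()`
#' reconstructs the object from the stored class tag.
#'
#' @param x an `msom` or `feasibility_net`.
#' @param path file path to write to / read from.
#' @return `save_snapshot()` returns `path` invisibly; `read_snapshot()`
#'   returns the reconstructed object.
#' @export
save_snapshot <- function(x, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("snapshot serialization needs the jsonlite package", call. = FALSE)
  }
  UseMethod("save_snapshot")
}

mat_out <- function(m) list(dim = dim(m), data = as.vector(m))
mat_in <- function(o) matrix(o$data, o$dim[1], o$dim[2])

#' @export
save_snapshot.msom <- function(x, path) {
  payload <- list(
    class = "msom",
    params = x[c("n", "m", "zeta", "iota", "nu", "lr_start", "lr_end",
                 "sigma_start", "sigma_end", "t_max", "t", "last_bmu")],
    Wt = mat_out(x$Wt), Ct = mat_out(x$Ct), c_map = x$c_map
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(path)
}

#' @export
save_snapshot.feasibility_net <- function(x, path) {
  payload <- list(
    class = "feasibility_net",
    params = x[c("lr", "n_in", "n_hidden", "n_actions")],
    W1 = mat_out(x$W1), b1 = x$b1, W2 = mat_out(x$W2), b2 = x$b2
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(path)
}

#' @rdname save_snapshot
#' @export
read_snapshot <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("snapshot serialization needs the jsonlite package", call. = FALSE)
  }
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(o$class, "msom")) {
    map <- msom(n = o$params$n, m = o$params$m, zeta = o$params$zeta,
                iota = o$params$iota, nu = o$params$nu,
                lr_start = o$params$lr_start, lr_end = o$params$lr_end,
                sigma_start = o$params$sigma_start, sigma_end = o$params$sigma_end,
                t_max = o$params$t_max, seed = 0)
    map$Wt <- mat_in(o$Wt); map$Ct <- mat_in(o$Ct)
    map$c_map <- as.numeric(o$c_map)
    map$t <- as.integer(o$params$t)
    map$last_bmu <- if (is.null(o$params$last_bmu)) NA_integer_ else
      as.integer(o$params$last_bmu)
    return(map)
  }
  if (identical(o$class, "feasibility_net")) {
    net <- feasibility_net(n_in = o$params$n_in, n_hidden = o$params$n_hidden,
                           n_actions = o$params$n_actions, lr = o$params$lr,
                           seed = 0)
    net$W1 <- mat_in(o$W1); net$b1 <- as.numeric(o$b1)
    net$W2 <- mat_in(o$W2); net$b2 <- as.numeric(o$b2)
    return(net)
  }
  stop("unknown snapshot class", call. = FALSE)
}
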