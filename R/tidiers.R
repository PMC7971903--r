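#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Gaussian encoder into one row per encoding vector
#'
#' @param x A `pib_gaussian_encoder`.
#' @param ... Unused.
#' @return A tibble with `row`, one column per input coordinate, `norm` and
#'   `active`.
#' @export
tidy.pib_gaussian_encoder <- function(x, ...) {
  A <- x$A
  colnames(A) <- paste0("a", seq_len(ncol(A)))
  out <- tibble::as_tibble(A)
  dplyr::mutate(out,
                row = dplyr::row_number(),
                norm = sqrt(rowSums(A^2)),
                active = .data$norm > 0,
                .before = 1)
}

#' @rdname tidy.pib_gaussian_encoder
#' @param joint Optional [joint_gaussian()] used to evaluate information
#'   coordinates.
#' @export
glance.pib_gaussian_encoder <- function(x, joint = NULL, ...) {
  base <- tibble::tibble(beta = x$beta,
                         rank = sum(rowSums(abs(x$A)) > 0))
  if (!is.null(joint)) {
    base <- dplyr::bind_cols(base, evaluate_encoder(x, joint))
  }
  base
}

#' Tidy a discrete encoder into long format
#'
#' @param x A `pib_discrete_encoder`.
#' @param ... Unused.
#' @return A tibble with columns `x` (grid value), `xtilde`, `q`.
#' @export
tidy.pib_discrete_encoder <- function(x, ...) {
  grid <- x$grid
  m <- x$m
  qv <- as.vector(x$q)
  tibble::tibble(
    x = rep(grid, times = m),
    xtilde = rep(seq_len(m), each = length(grid)),
    q = qv
  )
}

#' @rdname tidy.pib_discrete_encoder
#' @export
glance.pib_discrete_encoder <- function(x, ...) {
  tibble::tibble(m = x$m, beta = x$beta,
                 i_past_bits = x$i_past_bits,
                 i_future_bits = x$i_future_bits,
                 n_iter = x$n_iter, converged = x$converged)
}

#' Serialize an encoder to JSON
#'
#' Gaussian encoders are written as `{A, beta, source, i_past_bits,
#' i_future_bits}` (row-major `A`); discrete encoders as `{q, m, beta,
#' converged, i_past_bits, i_future_bits}`.
#'
#' @param encoder A gaussian or discrete encoder.
#' @param path Output file.
#' @param joint Optional joint used to stamp information coordinates on
#'   Gaussian encoders.
#' @return `path`, invisibly.
#' @export
write_encoder_json <- function(encoder, path, joint = NULL) {
  if (inherits(encoder, "pib_gaussian_encoder")) {
    info <- if (!is.null(joint)) evaluate_encoder(encoder, joint) else
      tibble::tibble(i_past_bits = NA_real_, i_future_bits = NA_real_)
    obj <- list(type = "gaussian",
                A = as.vector(t(encoder$A)), dim = dim(encoder$A),
                beta = encoder$beta,
                source = encoder$source[!vapply(encoder$source, is.function, TRUE)] %||% list(),
                i_past_bits = info$i_past_bits,
                i_future_bits = info$i_future_bits)
  } else if (inherits(encoder, "pib_discrete_encoder")) {
    obj <- list(type = "discrete",
                q = as.vector(t(encoder$q)), dim = dim(encoder$q),
                m = encoder$m, beta = encoder$beta,
                converged = encoder$converged,
                i_past_bits = encoder$i_past_bits,
                i_future_bits = encoder$i_future_bits)
  } else stop("not an encoder", call. = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an information curve as CSV
#'
#' Header `beta,i_past_bits,i_future_bits` (comma separated, '.' decimal).
#'
#' @param curve A `pib_info_curve` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[, intersect(
    c("beta", "i_past_bits", "i_future_bits", "converged"), names(curve))],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
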