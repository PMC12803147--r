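#' Template basis objects
#'
#' A `muap_basis` is the generative dictionary for multichannel motor-unit
#' action potentials (MUAPs): a shared set of orthonormal temporal
#' components `W` (`n_pcs` x `nt`), per-unit channel weights `U0`
#' (`n_units` x `n_channels` x `n_pcs`), an inverse whitening matrix
#' `w_inv` used to undo channel whitening when synthesising raw data, and a
#' positive scalar `b` converting bits into voltage units. The noiseless
#' template of unit *i* on all channels is `b * t(w_inv %*% (U0[i,,] %*% W))`.
#'
#' @param n_units,n_channels,nt,n_pcs Basis dimensions: units, channels,
#'   samples per spike window, and temporal principal components.
#' @param W Matrix `n_pcs x nt` with orthonormal rows.
#' @param U0 Array `n_units x n_channels x n_pcs` of channel weights.
#' @param w_inv Inverse whitening matrix `n_channels x n_channels`.
#' @param b Positive scalar bits-to-voltage conversion.
#' @param sampling_rate Sampling rate in Hz.
#' @param seed Seed recorded in the basis metadata (if any).
#' @return A `muap_basis` object.
#' @export
muap_basis <- function(W, U0, w_inv, b = 1, sampling_rate = 30000,
                       nt = ncol(W), n_pcs = nrow(W),
                       n_units = dim(U0)[1], n_channels = dim(U0)[2],
                       seed = NA_integer_) {
  basis <- structure(
    list(
      n_units = as.integer(n_units), n_channels = as.integer(n_channels),
      nt = as.integer(nt), n_pcs = as.integer(n_pcs),
      W = W, U0 = U0, w_inv = w_inv, b = as.double(b),
      sampling_rate = as.double(sampling_rate), seed = seed
    ),
    class = "muap_basis"
  )
  validate_basis(basis)
}

#' @rdname muap_basis
#' @param basis A `muap_basis` object to validate.
#' @export
validate_basis <- function(basis) {
  with(basis, {
    if (nt < 3L) stop("nt: spike window must have at least 3 samples")
    if (b <= 0) stop("b: bits-to-voltage scale must be positive")
    if (!identical(dim(W), c(n_pcs, nt))) {
      stop("W: expected dimensions ", n_pcs, " x ", nt)
    }
    if (!identical(dim(U0), c(n_units, n_channels, n_pcs))) {
      stop("U0: expected dimensions ", n_units, " x ", n_channels, " x ", n_pcs)
    }
    if (!identical(dim(w_inv), c(n_channels, n_channels))) {
      stop("w_inv: expected dimensions ", n_channels, " x ", n_channels)
    }
    gram <- tcrossprod(W)
    if (max(abs(gram - diag(n_pcs))) > 1e-8) {
      stop("W: rows are not orthonormal (tolerance 1e-8)")
    }
  })
  for (i in seq_len(basis$n_units)) {
    if (!all(is.finite(reconstruct_template(basis, i)))) {
      stop("U0: reconstructed template for unit ", i, " is not finite")
    }
  }
  invisible(basis)
}

#' Reconstruct the noiseless multichannel template of one unit
#'
#' @param basis A `muap_basis`.
#' @param unit Unit index (1-based).
#' @return Matrix `nt x n_channels`.
#' @export
reconstruct_template <- function(basis, unit) {
  A <- basis$U0[unit, , , drop = TRUE]
  dim(A) <- c(basis$n_channels, basis$n_pcs)
  basis$b * t(basis$w_inv %*% (A %*% basis$W))
}

# One Gabor-like atom: Gaussian-windowed sinusoid centred at `center`.
gabor_atom <- function(nt, center, width, freq, phase, amp) {
  t <- seq_len(nt) - center
  amp * exp(-(t^2) / (2 * width^2)) * sin(2 * pi * freq * t + phase)
}

#' Generate a synthetic template basis
#'
#' Builds a basis whose reconstructed templates emulate empirical
#' intramuscular MUAPs: multiphasic dominant-channel waveforms (sums of 2-3
#' Gaussian-windowed sinusoids), per-channel conduction delays of up to
#' `max_delay` samples (propagation along muscle fibres), and amplitude
#' decaying with channel distance from a random dominant channel. The
#' temporal components `W` are the top principal axes of the generated
#' per-channel traces and `U0` the least-squares loadings, so the
#' basis-reconstructed templates are self-consistent by construction.
#'
#' @inheritParams muap_basis
#' @param max_delay Maximum per-channel peak offset in samples (<= `nt/2`).
#' @param whiten If `TRUE`, attach a non-trivial symmetric positive-definite
#'   `w_inv` so the un-whitening path is exercised; default is the identity.
#' @param seed Integer seed; the generator is a pure function of all its
#'   arguments including the seed.
#' @return A `muap_basis`.
#' @examples
#' basis <- make_synthetic_basis(n_units = 3, n_channels = 8, seed = 1)
#' dim(reconstruct_template(basis, 1))
#' @export
make_synthetic_basis <- function(n_units = 10, n_channels = 8, nt = 61,
                                 n_pcs = 9, max_delay = 12, seed = 1,
                                 b = 1, sampling_rate = 30000,
                                 whiten = FALSE) {
  n_units <- assert_count(n_units, "n_units")
  n_channels <- assert_count(n_channels, "n_channels")
  nt <- assert_count(nt, "nt", min = 5L)
  n_pcs <- assert_count(n_pcs, "n_pcs")
  if (n_pcs > nt) stop("n_pcs must not exceed nt")
  if (max_delay > nt / 2) stop("max_delay must not exceed nt/2")

  build <- function(attempt) {
  templates <- with_seed(substream_seed(seed, paste0("basis", attempt)), {
    arr <- array(0, dim = c(n_units, n_channels, nt))
    for (i in seq_len(n_units)) {
      n_atoms <- sample(2:3, 1L)
      center0 <- nt / 3 + stats::runif(1, -2, 2)
      shape <- numeric(nt)
      for (a in seq_len(n_atoms)) {
        shape <- shape + gabor_atom(
          nt,
          center = center0 + stats::runif(1, -nt / 12, nt / 12),
          width = stats::runif(1, nt / 14, nt / 8),
          freq = stats::runif(1, 1.2, 2.2) / nt,
          phase = stats::runif(1, 0, 2 * pi),
          amp = stats::runif(1, 0.6, 1.4)
        )
      }
      shape <- shape / max(abs(shape)) * stats::runif(1, 60, 140)
      dominant <- sample.int(n_channels, 1L)
      delays <- if (max_delay > 0) {
        sample(seq(-max_delay, max_delay), n_channels, replace = TRUE)
      } else rep(0L, n_channels)
      delays[dominant] <- 0L
      decay_len <- max(1, n_channels / 3)
      for (ch in seq_len(n_channels)) {
        amp <- exp(-abs(ch - dominant) / decay_len)
        shifted <- numeric(nt)
        src <- seq_len(nt) - delays[ch]
        ok <- src >= 1L & src <= nt
        shifted[ok] <- shape[src[ok]]
        arr[i, ch, ] <- amp * shifted
      }
    }
    arr
  })

  # Temporal basis from PCA of all single-channel traces; loadings by
  # orthonormal projection so W/U0 are exactly consistent.
  traces <- matrix(aperm(templates, c(3, 2, 1)), nrow = nt)  # nt x (c*u)
  sv <- svd(traces, nu = min(nt, ncol(traces)))
  k <- min(n_pcs, ncol(sv$u))
  W <- t(sv$u[, seq_len(k), drop = FALSE])    # k x nt, orthonormal rows
  if (k < n_pcs) {                            # pad with orthogonal complement
    Q <- qr.Q(qr(cbind(t(W), diag(nt))))
    W <- t(Q[, seq_len(n_pcs), drop = FALSE])
  }
  U0 <- array(0, dim = c(n_units, n_channels, n_pcs))
  for (i in seq_len(n_units)) {
    U0[i, , ] <- templates[i, , ] %*% t(W)    # least squares: W rows orthonormal
  }

  w_inv <- diag(n_channels)
  if (whiten) {
    w_inv <- with_seed(substream_seed(seed, "whitening"), {
      R <- matrix(stats::rnorm(n_channels^2, sd = 0.15), n_channels)
      diag(n_channels) + crossprod(R)         # SPD, close to identity
    })
  }

  muap_basis(W = W, U0 = U0, w_inv = w_inv, b = b,
             sampling_rate = sampling_rate, seed = as.integer(seed))
  }

  # the PC truncation can occasionally smooth a unit below two sign
  # changes; regenerate (deterministically) until every reconstructed
  # dominant-channel waveform is multiphasic
  for (attempt in 0:25) {
    basis <- build(attempt)
    ok <- all(vapply(seq_len(n_units), function(u) {
      M <- reconstruct_template(basis, u)
      dom <- which.max(apply(abs(M), 2, max))
      v <- M[, dom]
      v <- v[abs(v) > 1e-3 * max(abs(v))]
      sum(diff(sign(v)) != 0) >= 2
    }, logical(1)))
    if (ok) return(basis)
  }
  stop("could not generate a multiphasic basis; widen nt or n_pcs")
}

#' Save or load a template basis container
#'
#' The container is a directory of named arrays (`W.npy`, `U0.npy`,
#' `w_inv.npy`) plus a JSON metadata member (`meta.json` with `n_units`,
#' `n_channels`, `nt`, `n_pcs`, `b`, `sampling_rate`, `seed`). A save/load
#' round trip reproduces every field bit-exactly; loading re-validates all
#' invariants and names the offending field on failure.
#'
#' @param basis A `muap_basis`.
#' @param path Directory path for the container.
#' @return `save_basis()` returns `path` invisibly; `load_basis()` returns
#'   the validated `muap_basis`.
#' @export
save_basis <- function(basis, path) {
  validate_basis(basis)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_npy(basis$W, file.path(path, "W.npy"))
  write_npy(basis$U0, file.path(path, "U0.npy"))
  write_npy(basis$w_inv, file.path(path, "w_inv.npy"))
  meta <- basis[c("n_units", "n_channels", "nt", "n_pcs", "b",
                  "sampling_rate", "seed")]
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_basis
#' @export
load_basis <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("basis container missing meta.json: ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("n_units", "n_channels", "nt", "n_pcs", "b", "sampling_rate")) {
    if (is.null(meta[[f]])) stop("basis metadata missing field: ", f)
  }
  arrays <- lapply(c(W = "W", U0 = "U0", w_inv = "w_inv"), function(nm) {
    fp <- file.path(path, paste0(nm, ".npy"))
    if (!file.exists(fp)) stop("basis container missing array: ", nm)
    read_npy(fp)
  })
  muap_basis(W = arrays$W, U0 = arrays$U0, w_inv = arrays$w_inv,
             b = meta$b, sampling_rate = meta$sampling_rate,
             nt = meta$nt, n_pcs = meta$n_pcs, n_units = meta$n_units,
             n_channels = meta$n_channels,
             seed = meta$seed %||% NA_integer_)
}

#' @export
print.muap_basis <- function(x, ...) {
  cat(sprintf(
    "<muap_basis> %d units, %d channels, nt=%d (%.2f ms at %g Hz), %d PCs, b=%g\n",
    x$n_units, x$n_channels, x$nt, 1000 * x$nt / x$sampling_rate,
    x$sampling_rate, x$n_pcs, x$b
  ))
  invisible(x)
}
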