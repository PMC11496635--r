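#' @keywords internal
"_PACKAGE"

# Electron rest mass in unified atomic mass units.
ELECTRON_MASS <- 0.00054857990907

#' Derive a reproducible child seed from a master seed and a label
#'
#' Named substreams keep stochastic steps (decoy sampling per formula,
#' per-dataset simulation, fold assignment) stable when unrelated parts of a
#' corpus change: the stream for `(purpose, formula)` depends only on the
#' master seed and the label, never on call order.
#'
#' @param master_seed integer master seed.
#' @param ... character or numeric labels identifying the stream
#'   (e.g. `"decoys"`, a molecular formula).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(42, "decoys", "C6H12O6")
derive_seed <- function(master_seed, ...) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  label <- paste(c(format(master_seed), vapply(list(...), as.character, "")),
                 collapse = "\r")
  bytes <- utf8ToInt(label)
  # 32-bit FNV-1a, kept in double arithmetic (exact below 2^53)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), as.integer(b))
    h <- (as.double(h) + 2^30) * 16777619
    h <- h %% 2^31
  }
  as.integer(h %% (2^31 - 1))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Symmetric closed ppm window half-width around mz.
ppm_window <- function(mz, tol_ppm) mz * tol_ppm / 1e6

`%||%` <- function(a, b) if (is.null(a)) b else a
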