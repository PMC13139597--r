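#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A^-1 directly from the pedigree by Henderson's rules, ignoring
#' inbreeding: each animal contributes 1/d to its own diagonal, -0.5/d to
#' animal-parent cells and 0.25/d between known parents, with d = 0.5 when
#' both parents are known, 0.75 with one and 1 with none. The pedigree must
#' be topologically ordered (parents before offspring); unknown parents are
#' coded 0 or NA.
#'
#' @param pedigree data.frame with columns `animal`, `sire`, `dam`.
#' @return sparse symmetric [Matrix::dsCMatrix-class] with dimnames the
#'   animal identifiers, in pedigree order.
#' @export
aInverse <- function(pedigree) {
  stopifnot(is.data.frame(pedigree), all(c("animal", "sire", "dam") %in% names(pedigree)))
  ids <- as.character(pedigree$animal)
  if (anyDuplicated(ids)) stop("duplicated animal ids in pedigree")
  n <- length(ids)
  idx <- function(p) {
    p <- as.character(p)
    out <- match(p, ids)
    out[is.na(p) | p %in% c("0", "")] <- NA_integer_
    out
  }
  si <- idx(pedigree$sire)
  di <- idx(pedigree$dam)
  known <- function(p, i) !is.na(p) & p < i  # parent must precede the animal
  bad <- which((!is.na(si) & si >= seq_len(n)) | (!is.na(di) & di >= seq_len(n)))
  if (length(bad))
    stop("pedigree not topologically ordered: animal(s) listed before a parent: ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (a in seq_len(n)) {
    s <- si[a]; d <- di[a]
    np <- sum(!is.na(c(s, d)))
    dd <- c(1, 0.75, 0.5)[np + 1L]
    w <- 1 / dd
    add(a, a, w)
    for (p in c(s, d)) {
      if (!is.na(p)) {
        add(a, p, -0.5 * w); add(p, a, -0.5 * w)
        add(p, p, 0.25 * w)
      }
    }
    if (!is.na(s) && !is.na(d)) {
      add(s, d, 0.25 * w); add(d, s, 0.25 * w)
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ids, ids))
  Matrix::forceSymmetric(Matrix::drop0(A))
}

# Reference-level-constrained fixed design: the first factor contributes a
# full indicator block, every later factor drops its first observed level;
# factors with a single observed level contribute nothing further.
fixedDesign <- function(factors) {
  stopifnot(length(factors) >= 1L)
  blocks <- list()
  for (k in seq_along(factors)) {
    f <- droplevels(as.factor(factors[[k]]))
    lev <- levels(f)
    keep <- if (k == 1L) lev else lev[-1]
    if (!length(keep)) next
    M <- Matrix::sparseMatrix(
      i = which(f %in% keep), j = match(f[f %in% keep], keep), x = 1,
      dims = c(length(f), length(keep)))
    colnames(M) <- paste0(names(factors)[k], keep)
    blocks[[length(blocks) + 1L]] <- M
  }
  do.call(cbind, blocks)
}

#' Solve Henderson's mixed-model equations
#'
#' Generic sparse MME solver shared by the test-day model and the
#' population model. For fixed design X and random blocks Z_b with prior
#' precision contributions Lambda_b (already scaled by the residual
#' variance, e.g. `sigma2_e * solve(G) \%x\% Ainv`), it factorizes
#' \deqn{C = W'W + blockdiag(0, Lambda)}
#' with W = \[X, Z_1, ...\] using Matrix's sparse Cholesky and returns the
#' solutions, fitted values and residuals. A singular fixed-effect block
#' (confounded factors after the reference-level constraints) raises an
#' error.
#'
#' @param X sparse or dense fixed-effect design matrix (n x p), already
#'   constrained to full column rank.
#' @param y numeric response vector.
#' @param randomBlocks list of blocks, each a list with elements `Z`
#'   (n x q design) and `lambda` (q x q precision, sparse), plus an
#'   optional `name`.
#' @return list with `beta` (fixed solutions, named), `u` (list of random
#'   solution vectors per block), `fitted`, `residuals`.
#' @export
solveMME <- function(X, y, randomBlocks = list()) {
  X <- methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")
  n <- length(y)
  stopifnot(nrow(X) == n)
  Zs <- lapply(randomBlocks, function(b)
    methods::as(Matrix::Matrix(b$Z, sparse = TRUE), "CsparseMatrix"))
  W <- if (length(Zs)) do.call(cbind, c(list(X), Zs)) else X
  C <- Matrix::crossprod(W)
  p <- ncol(X)
  qs <- vapply(Zs, ncol, integer(1))
  off <- p + c(0L, cumsum(qs))
  for (k in seq_along(Zs)) {
    rng <- (off[k] + 1L):(off[k + 1L])
    C[rng, rng] <- C[rng, rng] + randomBlocks[[k]]$lambda
  }
  rhs <- Matrix::crossprod(W, y)
  sol <- tryCatch(
    as.vector(Matrix::solve(Matrix::forceSymmetric(C), rhs)),
    error = function(e) {
      stop("mixed-model equations are singular; check for confounded fixed-effect ",
           "factors after the reference-level constraints (", conditionMessage(e), ")")
    })
  beta <- stats::setNames(sol[seq_len(p)], colnames(X))
  u <- vector("list", length(Zs))
  for (k in seq_along(Zs)) {
    rng <- (off[k] + 1L):(off[k + 1L])
    u[[k]] <- stats::setNames(sol[rng], colnames(Zs[[k]]))
    names(u)[k] <- randomBlocks[[k]]$name %||% paste0("block", k)
  }
  fitted <- as.vector(W %*% sol)
  list(beta = beta, u = u, fitted = fitted, residuals = y - fitted)
}
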