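#' Convert processed trade flows to primary equivalents
#'
#' Expresses flows of processed commodities as the mass of primary commodity
#' required to produce them (dividing by the extraction rate, i.e.
#' multiplying by the primary-per-processed factor) and accumulates them onto
#' the primary commodity. Only a single-level commodity tree is supported:
#' each processed commodity maps to exactly one primary.
#'
#' @param flows data.frame with columns `commodity, origin, dest, mass`.
#' @param conversion data.frame with columns `commodity, primary, factor`
#'   (factor = tonnes of primary per tonne of processed, > 0).
#' @return data.frame `commodity (primary), origin, dest, mass`, flows summed
#'   over processed streams mapping to the same primary.
#' @export
primary_equivalent_flows <- function(flows, conversion) {
  stopifnot(all(c("commodity", "origin", "dest", "mass") %in% names(flows)),
            all(c("commodity", "primary", "factor") %in% names(conversion)))
  unmapped <- setdiff(unique(flows$commodity), conversion$commodity)
  if (length(unmapped))
    stop("unmapped processed commodities: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  if (any(conversion$factor <= 0))
    stop("conversion factors must be > 0", call. = FALSE)
  idx <- match(flows$commodity, conversion$commodity)
  out <- data.frame(commodity = conversion$primary[idx],
                    origin = flows$origin, dest = flows$dest,
                    mass = flows$mass * conversion$factor[idx],
                    stringsAsFactors = FALSE)
  agg <- stats::aggregate(mass ~ commodity + origin + dest, data = out, FUN = sum)
  agg[order(agg$commodity, agg$origin, agg$dest), , drop = FALSE]
}

provenance_system <- function(production, trade, use = NULL) {
  P <- as.numeric(production)
  n <- length(P)
  T <- as.matrix(trade)
  if (!all(dim(T) == n)) stop("trade matrix does not match production vector",
                              call. = FALSE)
  if (any(T < 0)) stop("trade flows must be nonnegative", call. = FALSE)
  if (any(diag(T) != 0)) stop("self-flows are forbidden", call. = FALSE)
  supply <- P + colSums(T)
  exports <- rowSums(T)
  over <- exports > supply * (1 + 1e-9) & supply > 0
  if (any(over)) {
    warning(sprintf("%d countries export more than their supply; flows scaled down",
                    sum(over)))
    for (i in which(over)) T[i, ] <- T[i, ] * supply[i] / exports[i]
    supply <- P + colSums(T)
    exports <- rowSums(T)
  }
  nosupply <- supply <= 0
  if (!is.null(use) && any(nosupply & use > 0))
    warning("countries with zero supply but recorded use dropped from provenance")
  list(P = P, T = T, supply = supply, exports = exports, nosupply = nosupply)
}

#' Provenance shares via the re-export correction
#'
#' Traces traded commodities through intermediary countries back to primary
#' producers. Each country's supply is a mix of its own primary production
#' and the supply mixes of its import partners; exports carry the exporter's
#' supply mix. The origin-share matrix `F` therefore satisfies the fixed
#' point
#' \deqn{F[i,] = (P_i / s_i) e_i + \sum_j (T_{j \to i} / s_i) F[j,],}
#' with `s_i = P_i + imports_i`, solved here exactly as a dense linear
#' system. The same mix applies to domestic use and to exports, so the
#' returned matrix is the provenance portfolio of domestic use.
#'
#' @param production vector of primary production by country.
#' @param trade origin x destination flow matrix (same commodity, primary
#'   equivalents).
#' @param use optional domestic-use vector, used only to warn when a country
#'   with zero supply has recorded use.
#' @return matrix `S[consumer, origin]`; rows sum to 1 for countries with
#'   positive supply, `NA` rows for countries with no supply.
#' @export
provenance_shares <- function(production, trade, use = NULL) {
  sys <- provenance_system(production, trade, use)
  n <- length(sys$P)
  keep <- which(!sys$nosupply)
  S <- matrix(NA_real_, n, n, dimnames = dimnames(sys$T))
  if (length(keep)) {
    M <- t(sys$T[keep, keep, drop = FALSE]) / sys$supply[keep]  # M[i,j] = T[j->i]/s_i
    D <- diag(sys$P[keep] / sys$supply[keep], nrow = length(keep))
    A <- diag(length(keep)) - M
    if (abs(det(A)) < 1e-300)
      stop("provenance system is singular (pure re-export cycle with no production)",
           call. = FALSE)
    F <- solve(A, D)
    if (any(abs(rowSums(F) - 1) > 1e-6))
      stop("provenance solution is deficient (re-export cycle with no production)",
           call. = FALSE)
    S[keep, ] <- 0  # zero-supply countries cannot be origins
    S[keep, keep] <- F
  }
  if (!is.null(dimnames(sys$T))) dimnames(S) <- dimnames(sys$T)
  S
}

#' Provenance shares by fixed-point iteration
#'
#' Iterative flow-propagation counterpart of [provenance_shares()]: starts
#' from each country's own-production share and repeatedly pushes import
#' mixes through the network until convergence. Kept as an independent check
#' on the linear solve.
#'
#' @inheritParams provenance_shares
#' @param tol sup-norm convergence tolerance.
#' @param max_iter iteration cap.
#' @return matrix as in [provenance_shares()].
#' @export
provenance_shares_iterative <- function(production, trade, use = NULL,
                                        tol = 1e-13, max_iter = 100000L) {
  sys <- provenance_system(production, trade, use)
  n <- length(sys$P)
  keep <- which(!sys$nosupply)
  S <- matrix(NA_real_, n, n, dimnames = dimnames(sys$T))
  if (length(keep)) {
    M <- t(sys$T[keep, keep, drop = FALSE]) / sys$supply[keep]
    D <- diag(sys$P[keep] / sys$supply[keep], nrow = length(keep))
    F <- D
    for (it in seq_len(max_iter)) {
      Fn <- D + M %*% F
      if (max(abs(Fn - F)) < tol) { F <- Fn; break }
      F <- Fn
      if (it == max_iter)
        stop("provenance iteration did not converge (re-export cycle with no production?)",
             call. = FALSE)
    }
    if (any(abs(rowSums(F) - 1) > 1e-6))
      stop("provenance iteration converged to a deficient solution (re-export cycle with no production)",
           call. = FALSE)
    S[keep, ] <- 0
    S[keep, keep] <- F
  }
  S
}

#' Consumption-basis per-kg impacts from provenance shares
#'
#' Weights national production impacts by each consumer's provenance
#' portfolio: `w_i = sum_o S[i,o] v_o`. The result is a convex combination
#' of the origin production impacts, with the per-origin decomposition
#' retained.
#'
#' @param shares provenance matrix `S[consumer, origin]`.
#' @param production_impacts vector of per-kg production impacts by origin
#'   (dE/kg); must be available (non-`NA`) for every origin with positive
#'   share.
#' @return list with `value` (vector by consumer; `NA` where the consumer's
#'   share row is undefined) and `by_origin` (matrix `S * v` by consumer x
#'   origin).
#' @export
consumption_perkg_impact <- function(shares, production_impacts) {
  v <- as.numeric(production_impacts)
  if (ncol(shares) != length(v))
    stop("impact vector does not match share matrix", call. = FALSE)
  need <- !is.na(shares) & shares > 0
  missing_v <- which(is.na(v) & apply(need, 2, any))
  if (length(missing_v))
    stop("origins with positive share but no production impact: ",
         paste(colnames(shares)[missing_v], collapse = ", "), call. = FALSE)
  v0 <- ifelse(is.na(v), 0, v)
  by_origin <- sweep(shares, 2, v0, "*")
  list(value = as.numeric(by_origin %*% rep(1, length(v0))),
       by_origin = by_origin)
}
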