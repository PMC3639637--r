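#' Discrete velocity models D2Q9 and D3Q19
#'
#' Returns the discrete velocity set of the requested lattice: the integer
#' direction vectors e_i (with e_0 the rest direction), the quadrature
#' weights w_i, and the opposite-direction index map used by bounce-back.
#' The weights are the unique values satisfying the low-order moment
#' (isotropy) constraints sum(w) = 1, sum(w e) = 0,
#' sum(w e_a e_b) = (1/3) delta_ab; the test suite verifies these by direct
#' summation rather than trusting the constants.
#'
#' @param name `"D2Q9"` or `"D3Q19"`.
#' @return An object of class `lattice_model`: list with `name`, `q` (number
#'   of directions), `d` (spatial dimension), `e` (q x d integer matrix),
#'   `w` (length-q weights), `opp` (length-q integer map, `opp[i]` is the
#'   index of -e_i).
#' @examples
#' m <- lattice_model("D2Q9")
#' sum(m$w) # 1
#' @export
lattice_model <- function(name = c("D2Q9", "D3Q19")) {
  name <- match.arg(name)
  if (name == "D2Q9") {
    e <- rbind(
      c(0L, 0L),
      c(1L, 0L), c(0L, 1L), c(-1L, 0L), c(0L, -1L),
      c(1L, 1L), c(-1L, 1L), c(-1L, -1L), c(1L, -1L)
    )
    w <- c(4 / 9, rep(1 / 9, 4), rep(1 / 36, 4))
  } else {
    ax <- rbind(
      c(1L, 0L, 0L), c(-1L, 0L, 0L),
      c(0L, 1L, 0L), c(0L, -1L, 0L),
      c(0L, 0L, 1L), c(0L, 0L, -1L)
    )
    diag2 <- rbind(
      c(1L, 1L, 0L), c(-1L, -1L, 0L), c(1L, -1L, 0L), c(-1L, 1L, 0L),
      c(1L, 0L, 1L), c(-1L, 0L, -1L), c(1L, 0L, -1L), c(-1L, 0L, 1L),
      c(0L, 1L, 1L), c(0L, -1L, -1L), c(0L, 1L, -1L), c(0L, -1L, 1L)
    )
    e <- rbind(c(0L, 0L, 0L), ax, diag2)
    w <- c(1 / 3, rep(1 / 18, 6), rep(1 / 36, 12))
  }
  q <- nrow(e)
  # opposite map: index of the reversed direction vector
  opp <- vapply(seq_len(q), function(i) {
    which(colSums(t(e) != -e[i, ]) == 0L)[1]
  }, integer(1))
  structure(
    list(name = name, q = q, d = ncol(e), e = e, w = w, opp = opp),
    class = "lattice_model"
  )
}

#' @export
print.lattice_model <- function(x, ...) {
  cat(sprintf("<lattice_model %s: %d directions in %dD>\n", x$name, x$q, x$d))
  invisible(x)
}
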