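# Conference matrices for small even orders.
#
# A conference matrix C of order m has a single 0 in each row and column,
# +/-1 elsewhere, and satisfies C'C = (m-1) I. Orders 4, 6, 8 and 12 come
# from the Paley construction over GF(q), q = m - 1 prime; order 10 needs
# GF(9) and is stored as a verified literal; order 2 is trivial.

# Jacobsthal matrix over GF(q), q prime: Q[i, j] = chi(i - j)
jacobsthal <- function(q) {
  res <- unique((seq_len(q - 1)^2) %% q) # quadratic residues mod q
  chi <- function(a) {
    a <- a %% q
    if (a == 0) 0L else if (a %in% res) 1L else -1L
  }
  outer(0:(q - 1), 0:(q - 1),
        Vectorize(function(i, j) chi(i - j)))
}

paley_conference <- function(q) {
  Q <- jacobsthal(q)
  m <- q + 1L
  C <- matrix(0L, m, m)
  C[1L, 2:m] <- 1L
  C[2:m, 1L] <- if (q %% 4L == 1L) 1L else -1L # skew variant for q = 3 mod 4
  C[2:m, 2:m] <- Q
  C
}

# order-10 conference matrix from the Paley construction over GF(9),
# computed once and stored (GF(9) arithmetic is not worth runtime code)
conference_10 <- function() {
  rows <- c("0+++++++++",
            "+0+++--+--",
            "++0+-+--+-",
            "+++0--+--+",
            "++--0+++--",
            "+-+-+0+-+-",
            "+--+++0--+",
            "++--+--0++",
            "+-+--+-+0+",
            "+--+--+++0")
  t(vapply(strsplit(rows, ""), function(r)
    c(`0` = 0L, `+` = 1L, `-` = -1L)[r], integer(10)))
}

#' Construct a conference matrix
#'
#' Returns an order-`m` conference matrix: exactly one zero per row and
#' column, all other entries +/-1, satisfying `t(C) %*% C == (m - 1) * I`.
#' Small even orders are served from built-in verified constructions.
#'
#' @param order Even matrix order, one of 2, 4, 6, 8, 10, 12.
#' @return Integer matrix of class `conference_matrix`.
#' @examples
#' C <- conference_matrix(6)
#' crossprod(C) # 5 * diag(6)
#' @export
conference_matrix <- function(order) {
  if (length(order) != 1L || order != as.integer(order))
    stop("order must be a single integer", call. = FALSE)
  order <- as.integer(order)
  C <- switch(as.character(order),
    "2"  = matrix(c(0L, 1L, 1L, 0L), 2L, 2L),
    "4"  = paley_conference(3L),
    "6"  = paley_conference(5L),
    "8"  = paley_conference(7L),
    "10" = conference_10(),
    "12" = paley_conference(11L),
    stop("no conference-matrix construction available for order ", order,
         call. = FALSE))
  stopifnot(is_conference_matrix(C)) # every returned matrix is re-verified
  structure(C, class = c("conference_matrix", class(C)))
}

#' Check the conference-matrix invariants
#'
#' @param C A square matrix.
#' @return `TRUE` if `C` has one zero per row and column, +/-1 elsewhere,
#'   and satisfies `t(C) %*% C == (m - 1) * I`; otherwise `FALSE`.
#' @export
is_conference_matrix <- function(C) {
  m <- nrow(C)
  if (is.null(m) || m != ncol(C)) return(FALSE)
  if (!all(C %in% c(-1L, 0L, 1L))) return(FALSE)
  if (!all(rowSums(C == 0L) == 1L) || !all(colSums(C == 0L) == 1L))
    return(FALSE)
  all(crossprod(C) == (m - 1L) * diag(m))
}
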