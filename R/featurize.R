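#' Default atom featurizer
#'
#' Per-atom encoding used to build the initial feature matrix `X`:
#' one-hot atomic symbol over a fixed organic-chemistry vocabulary
#' (B, C, N, O, F, P, S, Cl, Br, I, other), one-hot heavy-atom degree
#' (0--5, clipped), and one-hot formal charge clipped to \[-2, 2\].
#' Hydrogens are implicit. Total width d0 = 11 + 6 + 5 = 22.
#'
#' @return A featurizer object (list with `width` and `encode(symbols,
#'   degrees, charges)`), consumed by [smiles_to_graph()].
#' @export
default_featurizer <- function() {
  vocab <- c("B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")
  n_sym <- length(vocab) + 1L        # + "other"
  n_deg <- 6L                        # degree 0..5
  n_chg <- 5L                        # charge -2..2
  width <- n_sym + n_deg + n_chg
  encode <- function(symbols, degrees, charges) {
    n <- length(symbols)
    X <- matrix(0, n, width)
    si <- match(symbols, vocab)
    si[is.na(si)] <- n_sym
    di <- pmin(pmax(as.integer(degrees), 0L), 5L) + 1L
    ci <- pmin(pmax(as.integer(charges), -2L), 2L) + 3L
    X[cbind(seq_len(n), si)] <- 1
    X[cbind(seq_len(n), n_sym + di)] <- 1
    X[cbind(seq_len(n), n_sym + n_deg + ci)] <- 1
    X
  }
  structure(list(width = width, encode = encode, vocab = vocab),
            class = "atom_featurizer")
}
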