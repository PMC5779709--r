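# Bundled example model networks (the simulation-study fixtures).

.example_strings <- list(
  # 5 taxa, one reticulation (R -> Q), gamma 0.7/0.3, ultrametric;
  # theta 0.006 on external branches and the root branch, 0.005 internal.
  net5_1ret = paste0(
    "[0.006](((((Q:0.004:0.006)I5#H1:0.002:0.005:0.7,A:0.006:0.006)",
    "I3:0.016:0.005,L:0.022:0.006)I2:0.02:0.005,(I5#H1:0.003:0.005:0.3,",
    "R:0.007:0.006)I4:0.035:0.005)I1:0.038:0.005,C:0.08:0.006);"),
  # 5 taxa, two reticulations (R -> Q and C -> A), gammas 0.7/0.3 and 0.6/0.4.
  net5_2ret = paste0(
    "[0.006](((((Q:0.004:0.006)I5#H1:0.002:0.005:0.7,(A:0.003:0.006)",
    "I6#H2:0.003:0.005:0.6)I3:0.016:0.005,L:0.022:0.006)I2:0.02:0.005,",
    "(I5#H1:0.003:0.005:0.3,R:0.014:0.006)I4:0.028:0.005)I1:0.038:0.005,",
    "(C:0.005:0.006,I6#H2:0.002:0.005:0.4)I7:0.075:0.005);"),
  # 4 taxa, one reticulation into C, gamma 0.8/0.2, theta 0.005 throughout.
  net4_1ret = paste0(
    "[0.005]((((C:0.005:0.005)I1#H1:0.006:0.005:0.8,D:0.011:0.005)",
    ":0.009:0.005,(B:0.014:0.005,I1#H1:0.009:0.005:0.2):0.006:0.005)",
    ":0.005:0.005,A:0.025:0.005);")
)

#' Bundled example networks
#'
#' Small model phylogenetic networks with published-style branch lengths,
#' per-branch population mutation rates and inheritance probabilities, used
#' throughout the documentation and the test suite:
#' \describe{
#'   \item{`net5_1ret`}{5 taxa (A, C, L, Q, R), one reticulation into Q with
#'     gamma 0.7/0.3; backbone tree (C,((L,(A,Q)),R)).}
#'   \item{`net5_2ret`}{the same backbone with a second reticulation into A,
#'     gamma 0.6/0.4.}
#'   \item{`net4_1ret`}{4 taxa (A, B, C, D), one reticulation into C with
#'     gamma 0.8/0.2.}
#' }
#'
#' @param name one of `"net5_1ret"`, `"net5_2ret"`, `"net4_1ret"`.
#' @param as_string return the rich Newick string instead of the parsed
#'   network.
#' @return A `"phylo_network"`, or a string when `as_string = TRUE`.
#' @export
example_network <- function(name = c("net5_1ret", "net5_2ret", "net4_1ret"),
                            as_string = FALSE) {
  name <- match.arg(name)
  s <- .example_strings[[name]]
  if (as_string) s else read_rich_newick(s)
}
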