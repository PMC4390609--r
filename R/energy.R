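#' Load the nearest-neighbour duplex energy model
#'
#' The packaged table holds Gibbs free energies (kcal/mol, 37 C) for the 36
#' stacks of two consecutive intermolecular base pairs, each pair written as
#' target base followed by miRNA base (Watson-Crick values from the
#' standard nearest-neighbour parameter set; G-U wobble stacks use a
#' simplified uniform value). Loop/bulge costs are affine and the duplex
#' carries an initiation penalty; both come from the configuration.
#'
#' @param path TSV with columns `pair1`, `pair2`, `dG`; defaults to the
#'   packaged table.
#' @param config a [default_config()] list supplying `duplexfold` penalties.
#' @return list of class `energy_model` with a 6x6 `stack` matrix (dimnames
#'   AU, UA, CG, GC, GU, UG), `initiation`, `loop_open`, `loop_extend`,
#'   `max_loop` and the source `table_path`.
#' @export
load_energy_model <- function(path = system.file("extdata",
                                                 "stack_energies.tsv",
                                                 package = "miRcons"),
                              config = default_config()) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  stack <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  stack[cbind(tab$pair1, tab$pair2)] <- tab$dG
  if (anyNA(stack)) stop("incomplete stack energy table: ", path)
  if (any(stack >= 0)) stop("stack energies must be negative")
  dp <- config$duplexfold
  if (dp$loop_open < 0 || dp$loop_extend < 0 || dp$initiation < 0) {
    stop("loop and initiation penalties must be non-negative")
  }
  structure(list(stack = stack, initiation = dp$initiation,
                 loop_open = dp$loop_open, loop_extend = dp$loop_extend,
                 max_loop = dp$max_loop, table_path = path),
            class = "energy_model")
}

# Pair label for target base x and miRNA base y, or NA if not pairable.
pair_label <- function(x, y) {
  lab <- paste0(x, y)
  ok <- lab %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  ifelse(ok, lab, NA_character_)
}

# Affine cost of an internal loop/bulge with u unpaired bases in total.
loop_cost <- function(u, model) {
  ifelse(u <= 0, 0, model$loop_open + model$loop_extend * u)
}
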