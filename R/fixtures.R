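# Packaged example networks and their attractor constraints.

#' Packaged example networks
#'
#' Three study systems ship with the package:
#'
#' * `"toy"` — a 5-gene toy network (genes A..E, 32 states) with two
#'   synthetic constraint states, `blue` = 10110 (index 22) and `red` =
#'   11101 (index 29). The constraint states are the published ones; the
#'   edge list itself is a figure-style reconstruction (the original wiring
#'   is shown only graphically) built so that both constraint states are
#'   attainable as attractors under the \{AND_HI, OR_HI\} pair, with gene C
#'   regulated by B and E as in the original.
#' * `"mef_ipsc"` — the 14-node network (13 transcription factors + the
#'   medium LIF, 16384 states) governing reprogramming of mouse embryonic
#'   fibroblasts to induced pluripotent stem cells, transcribed verbatim
#'   from the published 38-edge interaction table. Its constraint file is a
#'   synthetic stand-in: the published binarized patterns for MEF, the
#'   NG-negative roadblock and iPSC appear only in a figure.
#' * `"pluripotency"` — a 15-node network (12 transcription factors + media
#'   LIF, CH, PD; 32768 states) for maintenance of naive pluripotency;
#'   edges and constraints are synthetic reconstructions following the
#'   published textual description and reproducing the published in-degree
#'   profile (so that the total configuration count with six operators is
#'   exactly 28179280429056).
#'
#' @param name `"toy"`, `"mef_ipsc"` or `"pluripotency"`.
#' @return List with elements `grn` (a [grn()]) and `constraints`
#'   (a [constraint_set()]).
#' @examples
#' fx <- fixture("toy")
#' n_genes(fx$grn)
#' @export
fixture <- function(name = c("toy", "mef_ipsc", "pluripotency")) {
  name <- match.arg(name)
  files <- switch(name,
    toy = c("toy_edges_synthetic.tsv", "toy_constraints.json"),
    mef_ipsc = c("mef_ipsc_edges.tsv", "mef_ipsc_constraints_synthetic.json"),
    pluripotency = c("pluripotency_edges_synthetic.tsv",
                     "pluripotency_constraints_synthetic.json")
  )
  path <- function(f) system.file("extdata", f, package = "enscape", mustWork = TRUE)
  list(grn = read_network(path(files[1])),
       constraints = read_constraints(path(files[2])))
}
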