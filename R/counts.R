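#' Printed preBotzinger Complex neuron counts
#'
#' The cell counts underlying the "how few neurons" arithmetic: from
#' single-cell profiling of the neonatal ventrolateral medulla, 1817 cells
#' were profiled of which 267 were presumed preBotC neurons and 21 of
#' those expressed the mu-opioid receptor; immunostaining of one preBotC
#' resolved the receptor-expressing glutamatergic neurons into 92
#' Dbx1-only, 50 Dbx1/FOXP2 and 20 FOXP2-only cells.
#'
#' @return A list with `n_cells`, `n_prebotc_neurons`, `n_oprm1_neurons`,
#'   and `glut_subtypes` (named vector: `dbx1_only`, `dbx1_foxp2`,
#'   `foxp2_only`).
#' @export
prebotc_neuron_counts <- function() {
  list(
    n_cells = 1817L,
    n_prebotc_neurons = 267L,
    n_oprm1_neurons = 21L,
    glut_subtypes = c(dbx1_only = 92L, dbx1_foxp2 = 50L, foxp2_only = 20L)
  )
}

#' Derived neuron-count summaries
#'
#' Arithmetic on preBotC cell counts: the percentage of presumed preBotC
#' neurons expressing the mu-opioid receptor, and the sizes of the
#' candidate rescue populations (the FOXP2 lineage, the Dbx1 lineage, and
#' all receptor-expressing glutamatergic neurons).
#'
#' @param counts A list shaped like [prebotc_neuron_counts()].
#' @return A one-row tibble with `oprm1_pct`, `n_foxp2_lineage`,
#'   `n_dbx1_lineage`, `n_glutamatergic`.
#' @export
#' @examples
#' summarize_neuron_counts()
summarize_neuron_counts <- function(counts = prebotc_neuron_counts()) {
  g <- counts$glut_subtypes
  tibble(
    oprm1_pct = 100 * counts$n_oprm1_neurons / counts$n_prebotc_neurons,
    n_foxp2_lineage = unname(g[["dbx1_foxp2"]] + g[["foxp2_only"]]),
    n_dbx1_lineage = unname(g[["dbx1_only"]] + g[["dbx1_foxp2"]]),
    n_glutamatergic = sum(g)
  )
}
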