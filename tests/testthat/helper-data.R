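# Small in-code builders for hand-pollination tables used across tests.

make_bout <- function(visits, id = "b1", pollinator = "moth") {
  list(bout_id = id, pollinator = pollinator, visits = visits)
}

make_bouts <- function(...) {
  structure(list(...), class = "foraging_bouts")
}

make_pistils <- function(direction, stigma_i, style_i, ovary_i,
                         stigma_j, style_j, ovary_j) {
  n_i <- length(stigma_i)
  n_j <- length(stigma_j)
  data.frame(
    pistil_id = sprintf("p%02d", seq_len(n_i + n_j)),
    maternal_species = direction[1],
    paternal_species = rep(c(direction[1], direction[2]), c(n_i, n_j)),
    treatment = rep(c("intra_cross", "inter_cross"), c(n_i, n_j)),
    tubes_on_stigma = c(stigma_i, stigma_j),
    tubes_in_style = c(style_i, style_j),
    tubes_in_ovary = c(ovary_i, ovary_j),
    stringsAsFactors = FALSE
  )
}

make_fruits <- function(direction, flowers_intra, set_intra,
                        flowers_inter, set_inter) {
  data.frame(
    maternal_species = direction[1],
    paternal_species = c(direction[1], direction[2]),
    treatment = c("intra_cross", "inter_cross"),
    flowers_treated = c(flowers_intra, flowers_inter),
    fruits_set = c(set_intra, set_inter),
    stringsAsFactors = FALSE
  )
}

make_seeds <- function(direction, large_i, small_i, aborted_i, empty_i,
                       large_j, small_j, aborted_j, empty_j) {
  n_i <- length(large_i)
  n_j <- length(large_j)
  data.frame(
    fruit_id = sprintf("f%02d", seq_len(n_i + n_j)),
    maternal_species = direction[1],
    paternal_species = rep(c(direction[1], direction[2]), c(n_i, n_j)),
    treatment = rep(c("intra_cross", "inter_cross"), c(n_i, n_j)),
    n_large = c(large_i, large_j),
    n_small = c(small_i, small_j),
    n_aborted = c(aborted_i, aborted_j),
    n_empty = c(empty_i, empty_j),
    stringsAsFactors = FALSE
  )
}

# Independent oracle for the G statistic, written from the definition.
g_oracle <- function(o1, o2) {
  e <- (o1 + o2) / 2
  o <- c(o1, o2)
  2 * sum(ifelse(o > 0, o * log(o / e), 0))
}
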