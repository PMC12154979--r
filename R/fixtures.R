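#' Long-chain crowding scenarios
#'
#' The three cell-like scenarios for long heterogeneous duplexes: chains of
#' 50, 100 and 300 bp carrying five crowders of graded strength
#' (alpha = 5, 6, 7, 8, 9) at fixed positions — (33, 36, 27, 15, 43),
#' (83, 86, 77, 15, 93) and (283, 286, 177, 115, 293) respectively — so
#' the crowded fraction of sites falls from 10% to 5% to 5/300 (about
#' 1.7%) as the chain grows. The underlying base-pair sequences are not
#' part of the published record, so each scenario draws a seeded random
#' heteropolymer at 50% GC via [generate_random_duplex()]; the sequence is
#' therefore synthetic and reproducible, not the original one.
#'
#' @param n chain length: 50, 100 or 300.
#' @param gc_fraction GC content of the synthetic sequence.
#' @param seed seed for the synthetic sequence.
#' @return List with \code{duplex}, \code{crowders}, \code{crowded_fraction}.
#' @examples
#' sc <- long_chain_scenario(50)
#' sc$crowded_fraction  # 0.1
#' @export
long_chain_scenario <- function(n = c(50, 100, 300), gc_fraction = 0.5,
                                seed = 2025) {
  n <- match.arg(as.character(n[1]), c("50", "100", "300"))
  sites <- switch(n,
                  "50"  = c(33, 36, 27, 15, 43),
                  "100" = c(83, 86, 77, 15, 93),
                  "300" = c(283, 286, 177, 115, 293))
  n <- as.integer(n)
  duplex <- generate_random_duplex(n, gc_fraction, seed = seed,
                                   label = sprintf("scenario-%dbp", n))
  crowders <- crowder_config(sites, alpha = c(5, 6, 7, 8, 9))
  list(duplex = duplex, crowders = crowders,
       crowded_fraction = length(sites) / n)
}

#' Write the scenario fixture files
#'
#' Emits the two short 8-bp duplexes (chain-A GGGAGAAG, chain-B GGAAGAGG)
#' as FASTA in shorthand alphabet, plus one YAML config per long-chain
#' scenario holding the crowder positions/strengths, chain length, GC
#' fraction and sequence seed.
#'
#' @param dir output directory (created if needed).
#' @param gc_fraction,seed forwarded to [long_chain_scenario()].
#' @return Invisibly, the vector of written paths.
#' @export
write_scenario_fixtures <- function(dir, gc_fraction = 0.5, seed = 2025) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (ch in list(c("chain-A", "GGGAGAAG"), c("chain-B", "GGAAGAGG"))) {
    p <- file.path(dir, paste0(ch[1], ".fasta"))
    writeLines(c(paste0(">", ch[1], " shorthand G=GC A=AT"), ch[2]), p)
    paths <- c(paths, p)
  }
  for (n in c(50, 100, 300)) {
    sc <- long_chain_scenario(n, gc_fraction, seed)
    cfg <- list(
      label = sc$duplex$label,
      length = n,
      gc_fraction = gc_fraction,
      sequence_seed = seed,
      sequence = format_duplex(sc$duplex),
      crowded_fraction = sc$crowded_fraction,
      crowders = lapply(seq_along(sc$crowders$sites), function(i) {
        list(site = sc$crowders$sites[i], alpha = sc$crowders$alpha[i])
      })
    )
    p <- file.path(dir, sprintf("scenario-%dbp.yaml", n))
    yaml::write_yaml(cfg, p, precision = 12)
    paths <- c(paths, p)
  }
  invisible(paths)
}
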