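# Hand-built transcript models and random profiles used across tests.

# Single-exon model: exon 101..500 (400 nt transcript), CDS at transcript
# positions 31..330 with the stop codon starting at 328; the 70 nt 3'UTR
# leaves room for the full downstream TSI flank.
make_plus_model <- function(id = "TXP") {
  transcript_model(id, paste0(id, "_G"), "chr1", "+",
                   data.frame(start = 101L, end = 500L),
                   cds_start_t = 31L, stop_codon_start_t = 328L)
}

make_minus_model <- function(id = "TXM") {
  transcript_model(id, paste0(id, "_G"), "chr1", "-",
                   data.frame(start = 101L, end = 500L),
                   cds_start_t = 31L, stop_codon_start_t = 328L)
}

# A profile long/deep enough for a full default TSI window around the stop.
uniform_profile <- function(model, value = 5L) {
  rep(as.integer(value), model$length_t)
}

random_profile <- function(model, lambda = 2) {
  as.integer(rpois(model$length_t, lambda))
}

# a small bank of spliced models on both strands for coordinate tests
spliced_models <- function() {
  list(
    A = transcript_model("A", "GA", "chr1", "+",
                         data.frame(start = c(11L, 61L, 201L),
                                    end = c(40L, 100L, 330L)),
                         cds_start_t = 21L, stop_codon_start_t = 180L),
    B = transcript_model("B", "GB", "chr1", "-",
                         data.frame(start = c(501L, 701L),
                                    end = c(650L, 800L)),
                         cds_start_t = 31L, stop_codon_start_t = 202L),
    C = transcript_model("C", "GC", "chr2", "-",
                         data.frame(start = c(101L, 301L, 401L),
                                    end = c(220L, 360L, 520L)),
                         cds_start_t = 41L, stop_codon_start_t = 230L))
}

# fake tsi_table with given genotype means, for target-calling tests
fake_tsi_table <- function(genotype_means) {
  structure(list(records = data.frame(), genotype_means = genotype_means,
                 params = tsi_params()),
            class = "tsi_table")
}
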