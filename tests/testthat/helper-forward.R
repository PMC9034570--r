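# Shared helpers: forward-simulate observable ratios from (k, x) or from
# a rate triplet, used to derive oracle values inside the tests.

forward_ratios <- function(k, x) {
  c(a = ratio_unlabeled(k, x), b = ratio_labeled(k, x))
}

forward_record <- function(alpha, beta, gamma, labeling_time,
                           transcript_id = "TX1", gene_id = "G1") {
  forward_observe(
    data.frame(transcript_id = transcript_id, gene_id = gene_id,
               alpha = alpha, beta = beta, gamma = gamma,
               stringsAsFactors = FALSE),
    labeling_time)
}
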