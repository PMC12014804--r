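# shared fixtures: WT-magnitude parameters and protocols used across tests
wt_enrichment <- function() enrichment_spec(alpha_f = 0.13, alpha_i = 0.0007)
s3_protocol <- function() flash_protocol("S3")
s2_protocol <- function(k_f_s3 = 29) flash_protocol("S2", k_f_s3 = k_f_s3)
wt_s2_truth <- function() exchange_params(k_f = 111, k_s = 0.93)
wt_fluor_truth <- function()
  fluor_decay_params(A0 = 0.02, A1 = 0.07, A2 = 0.37, A3 = 0.54,
                     tau1 = 3.5e-3, tau2 = 0.289, tau3 = 1.5)
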