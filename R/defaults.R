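#' Pipeline parameter defaults
#'
#' All tunable thresholds of the workflow with their default values,
#' in one place so a run configuration can be recorded and so the
#' defaults stay consistent between the R functions and the command
#' line interface.
#'
#' @return Named list of defaults.
#' @export
utrkit_defaults <- function() {
  list(
    peak_radius = 30,             # nt, local-mode merge radius
    rpm_threshold = 5,            # reads per million, strict >
    classify_window = 40,         # nt, centered window at 3' ends
    cluster_tpm_min = 3,          # external atlas cluster TPM
    priming_window = 20,          # nt downstream, internal priming
    priming_a_frac = 0.65,        # A-fraction fail threshold
    priming_a_run = 8,            # consecutive-A fail threshold
    five_ext = 1000,              # nt upstream extension
    three_ext = 5000,             # nt downstream extension
    truncation_length = 500,      # nt kept from the 3' end
    dedup_distance = 50,          # nt, strict <
    merge_distance = 200,         # nt, strict <
    read_length = 100,            # nt
    dist_mean = 300,              # nt, gamma read-distance mean
    dist_sd = 100,                # nt, gamma read-distance sd
    minor_celltypes = 10,         # minor CS rule (count)
    min_isoform_frac = 0.10,      # qualifying isoform fraction
    switch_min_cells = 200,       # cells per cell type
    switch_min_tpm = 5,           # gene TPM
    fc_threshold = 1.5,           # DGE fold change
    dwui_threshold = 0.10,        # DUL effect size
    q_threshold = 0.05,           # FDR
    n_boot_ci = 2000,             # bootstrap CI samples
    min_cells_per_gene = 50,      # bootstrap coexpression minimum
    effect_min_cells = 30,        # perturbation cell minimum
    effect_tpm_min = 5,           # effect-average TPM filter
    effect_band = c(0.1, 0.9),    # baseline WUI/IPA band
    zscale_max_nondetect = 0.2,   # clustering gene filter
    zscale_min_tpm = 20,          # clustering gene filter
    n_pcs = 30,                   # clustering PCs
    knn_k = c(5, 4, 3),           # kNN k per clustering round
    compensation_shift = 0.5,     # Eq. band: -0.5 >= ratio >= -2
    slam_timepoints = c(0, 120, 240, 360)  # minutes
  )
}
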