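# Shared simulated fixtures, built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

fixture_adapter <- "TGGAATTCTCGGGTGCCAAGG"

# Seeded 5-precursor dataset with planted miR/star/moR/loop truth,
# canonical-only reads, all counts >= MIN_COUNT; plus the pipeline run on it.
shared_sim_run <- function() {
  if (!is.null(.fixture_cache$run)) return(.fixture_cache$run)
  dir <- file.path(tempdir(), "morquant_fixture")
  sd <- simulate_dataset(dir, seed = 42L)
  cfg <- run_config(samples = c(s1 = unname(sd$paths[["fastq"]])),
                    genome = unname(sd$paths[["genome"]]),
                    annotation = unname(sd$paths[["annotation"]]),
                    ADAPTER = fixture_adapter,
                    outdir = file.path(dir, "out"))
  res <- run_pipeline(cfg)
  .fixture_cache$run <- list(sd = sd, cfg = cfg, res = res, dir = dir)
  .fixture_cache$run
}

# Dataset with borderline-planted moRs: one moR at count 5 (< MIN_COUNT=10)
# and one moR whose reads have flat Phred 28 (< MEAN_QUAL_FILTER=30, but
# >= 26).
borderline_sim <- function() {
  if (!is.null(.fixture_cache$borderline)) return(.fixture_cache$borderline)
  dir <- file.path(tempdir(), "morquant_borderline")
  sd <- simulate_dataset(dir, seed = 7L,
                         qual_model = list(
                           phred = 40L,
                           per_srna = c("moR-2-5p" = 28L),
                           count_overrides = list("moR-4-3p" = 5L)))
  .fixture_cache$borderline <- list(sd = sd, dir = dir)
  .fixture_cache$borderline
}
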