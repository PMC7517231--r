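R ?= Rscript

install:
	R CMD INSTALL --no-docs --no-html --no-help .

test:
	$(R) -e 'testthat::test_dir("tests/testthat", package = "sampenprof", load_package = "installed")'

acceptance:
	$(R) scripts/acceptance.R --seed 1 --out results/acceptance.json

# Full-scale replication: both processes, 11 levels (including 0),
# 100 replicates of 4000 samples, 200 radii; writes profiles, crossing
# reports, consistency regions and a checksummed manifest.
paper:
	$(R) -e 'library(sampenprof); run_paper_experiment("results/paper", replicates = 100, N = 4000, levels = seq(0, 1, by = 0.1), base_seed = 1)'

.PHONY: install test acceptance paper
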