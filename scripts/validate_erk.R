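#!/usr/bin/env Rscript
# Optional validation against the 99-species ERK activation model (obtain
# the SBML from its public repository accession; not vendored). The rate of
# EGF binding is the input (parameter-scale) and total doubly/singly
# phosphorylated ERK the output. The published analysis stabilised the
# model by giving the total-proteasome state a depletion reaction; because
# the depletion rate constant is not stated, it is exposed here as
# --proteasome-depletion (per second) applied to --proteasome-species.
#
# Runtime is tens of minutes on one CPU; this script is not part of the
# test suite.
#
# Usage:
#   Rscript scripts/validate_erk.R --model BIOMD0000000049.xml \
#     --input <EGF-binding rate parameter> \
#     --output "ppERK + dppERK + ppERK_MKP3 + dppERK_MKP3" \
#     [--proteasome-species <id>] [--proteasome-depletion 1e-3] \
#     [--step 0.5] [--t-end 6000] [--chi-c 250] [--max-error 0.05] [--seed 1]

suppressMessages(library(netreduce))

args <- commandArgs(trailingOnly = TRUE)
get_opt <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i)) default else args[i + 1L]
}
model_path <- get_opt("--model")
if (is.null(model_path) || !file.exists(model_path)) {
  stop("supply --model <sbml file> (download the ERK model from its accession)")
}
input_id <- get_opt("--input")
output_expr <- get_opt("--output")
stopifnot(!is.null(input_id), !is.null(output_expr))

net <- read_sbml(model_path)

# stabilising modification: first-order depletion of the proteasome pool
prot <- get_opt("--proteasome-species")
if (!is.null(prot)) {
  kdep <- as.numeric(get_opt("--proteasome-depletion", "1e-3"))
  net$parameters <- c(net$parameters, k_proteasome_depletion = kdep)
  net$reactions <- c(net$reactions, list(reaction(
    stats::setNames(1L, prot), stats::setNames(integer(0), character(0)),
    str2lang(sprintf("k_proteasome_depletion * %s", prot)),
    id = "proteasome_depletion")))
}

spec <- io_spec(
  inputs = list(list(id = input_id, mode = "parameter-scale")),
  output = output_expr)
# default protocol: 50% inhibition of EGF binding from the steady state
protocol <- error_protocol(u = as.numeric(get_opt("--step", "0.5")),
                           t_end = as.numeric(get_opt("--t-end", "6000")))
config <- reduction_config(
  max_error = as.numeric(get_opt("--max-error", "0.05")),
  chi_c = as.numeric(get_opt("--chi-c", "250")),
  design = perturbation_design(n_sims = 50L, range = c(0.4, 1.6),
                               seed = as.integer(get_opt("--seed", "1"))),
  seed = as.integer(get_opt("--seed", "1")))

rep <- run_combined_reduction(net, spec, protocol, config)
print(rep)
cat(sprintf("conservation relations: %d (=> %d ODEs)\n",
            nrow(rep$conservation$gamma), length(rep$conservation$retained)))
cat(sprintf("chi (conservation-reduced, x0): %.1f\n", rep$conservation$chi))
cat(sprintf("lumping halted at %d states (chi = %.1f)\n",
            rep$lumping$system$n, rep$lumping$chi))
cat(sprintf("final model: %d states, E = %.3g%%\n",
            rep$final$dim, 100 * rep$final$E))
if (!is.null(rep$indices)) print(rep$indices)
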