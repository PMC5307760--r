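#!/usr/bin/env Rscript
# Optional validation against an 11-species chemotactic signalling model of
# E. coli (not shipped with the package; supply your own SBML transcription).
# The attractant concentration is the input and total phosphorylated CheY
# (free and in complex) the output. Reported: number of conservation
# relations, stiffness at the initial condition of the conservation-reduced
# realisation, the dimension at which lumping halts under chi_c, and the
# final combined-reduction error under a step of attractant at t = 0.
#
# Usage:
#   Rscript scripts/validate_chemotaxis.R --model chemotaxis.xml \
#     --input <ligand-species-or-rate-parameter> \
#     --output "CheYp + CheA_CheYp + CheYp_CheZ" \
#     [--input-mode additive-rate|parameter-scale] [--step 10] \
#     [--t-end 3] [--chi-c 250] [--max-error 0.05] [--seed 1]

suppressMessages(library(netreduce))

args <- commandArgs(trailingOnly = TRUE)
get_opt <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i)) default else args[i + 1L]
}
model_path <- get_opt("--model")
if (is.null(model_path) || !file.exists(model_path)) {
  stop("supply --model <sbml file> (the chemotaxis model is not vendored)")
}
input_id <- get_opt("--input")
output_expr <- get_opt("--output")
stopifnot(!is.null(input_id), !is.null(output_expr))

net <- read_sbml(model_path)
spec <- io_spec(
  inputs = list(list(id = input_id,
                     mode = get_opt("--input-mode", NULL))),
  output = output_expr)
protocol <- error_protocol(u = as.numeric(get_opt("--step", "10")),
                           t_end = as.numeric(get_opt("--t-end", "3")))
config <- reduction_config(
  max_error = as.numeric(get_opt("--max-error", "0.05")),
  chi_c = as.numeric(get_opt("--chi-c", "250")),
  seed = as.integer(get_opt("--seed", "1")))

rep <- run_combined_reduction(net, spec, protocol, config)
print(rep)
cat(sprintf("conservation relations: %d\n", nrow(rep$conservation$gamma)))
cat(sprintf("dim after conservation: %d\n", length(rep$conservation$retained)))
cat(sprintf("chi (conservation-reduced, x0): %.1f\n", rep$conservation$chi))
cat(sprintf("lumping halted at %d states (chi = %.1f)\n",
            rep$lumping$system$n, rep$lumping$chi))
cat(sprintf("final model: %d states, E = %.3g%%\n",
            rep$final$dim, 100 * rep$final$E))
if (!is.null(rep$indices)) print(rep$indices)
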