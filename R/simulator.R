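#' Default SNPs-per-gene frequency table
#'
#' A plausible distribution of the number of heterozygous SNPs per gene in
#' an allele-resolved RNA-seq table: mode at 2–5 SNPs with a long right
#' tail to ~50 (negative-binomial shaped, shifted so every gene has at
#' least two SNPs).
#'
#' @return data frame with columns `J` (2..50) and `weight`.
#' @export
default_snp_table <- function() {
  J <- 2:50
  w <- stats::dnbinom(J - 2L, size = 1.2, mu = 4)
  data.frame(J = J, weight = w / sum(w))
}

#' Simulation configuration
#'
#' Defines the generative conditions of the synthetic-genome study: equal
#' blocks of genes from the four candidate models, gene effects drawn from
#' a fixed grid of log-odds, variance components drawn from inverse-gamma
#' priors, and total counts drawn from a log-normal hierarchy whose
#' mean–dispersion coupling follows the two fitted log-linear relations
#' (intercept/slope `alpha1`/`alpha2` across SNPs within a gene,
#' `alpha3`/`alpha4` across replicates within a SNP).
#'
#' `snp_sd_mode` controls how the fitted relation is turned into a
#' log-normal spread: `"count-sd"` (default) reads
#' \eqn{\exp(\alpha_1 + \alpha_2 \log \bar n)} as the count-scale standard
#' deviation and converts it to the matching log-normal `sdlog`;
#' `"literal"` uses \eqn{\alpha_1 + \alpha_2 \log \bar n} directly as the
#' log-scale SD (counts are then capped at `count_cap` to stay
#' representable).
#'
#' @param G total number of genes.
#' @param genes_per_model 4-vector of genes per model (must sum to `G`).
#' @param K biological replicates per gene.
#' @param alpha1,alpha2 intercept/slope of the log-linear mean–SD relation
#'   of per-SNP mean counts within a gene.
#' @param alpha3,alpha4 same for per-cell counts within a SNP.
#' @param beta_grid gene-effect grid sampled uniformly for models 2 and 4.
#' @param hp generating [hyperparameters()] (the inverse-gamma components
#'   drive the variance draws).
#' @param base_meanlog,base_sdlog log-normal law of the per-gene mean total
#'   count \eqn{\bar n_g}.
#' @param snp_table SNPs-per-gene frequency table (`J`, `weight`).
#' @param snp_sd_mode `"count-sd"` or `"literal"` (see Details).
#' @param sd_floor floor for any derived SD.
#' @param count_cap cap on simulated total counts (only binding under
#'   `"literal"`).
#' @param seed base seed; each replicate uses a sub-stream derived from it.
#' @param n_sims number of simulation replicates for [run_study()].
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(G = 4000L, genes_per_model = NULL, K = 4L,
                       alpha1 = -0.36, alpha2 = 0.97,
                       alpha3 = -0.53, alpha4 = 0.77,
                       beta_grid = c(-4.39, -1.20, -0.41, 0.41, 1.20, 4.39),
                       hp = hyperparameters(mu = 0.43, sigma2 = 4.62,
                                            a_s = 2.35, b_s = 1.37,
                                            a_r = 2.03, b_r = 0.09),
                       base_meanlog = log(50), base_sdlog = 1.2,
                       snp_table = default_snp_table(),
                       snp_sd_mode = c("count-sd", "literal"),
                       sd_floor = 0.01, count_cap = 1e9,
                       seed = 1L, n_sims = 10L) {
  if (is.null(genes_per_model)) {
    stopifnot(G %% 4L == 0L)
    genes_per_model <- rep(G %/% 4L, 4L)
  }
  stopifnot(sum(genes_per_model) == G, K >= 2L,
            all(snp_table$J >= 2L), all(snp_table$weight >= 0))
  structure(
    list(G = as.integer(G), genes_per_model = as.integer(genes_per_model),
         K = as.integer(K), alpha1 = alpha1, alpha2 = alpha2,
         alpha3 = alpha3, alpha4 = alpha4, beta_grid = beta_grid, hp = hp,
         base_meanlog = base_meanlog, base_sdlog = base_sdlog,
         snp_table = snp_table, snp_sd_mode = match.arg(snp_sd_mode),
         sd_floor = sd_floor, count_cap = count_cap,
         seed = as.integer(seed), n_sims = as.integer(n_sims)),
    class = "sim_config")
}

# log-normal spread implied by the fitted mean-SD relation
lognormal_sd <- function(log_mean, a, b, mode, floor) {
  if (mode == "literal") {
    pmax(a + b * log_mean, floor)
  } else {
    s_over_m <- exp(a + b * log_mean - log_mean)  # count-scale SD / mean
    pmax(sqrt(log1p(s_over_m^2)), floor)
  }
}

round_count <- function(x, cap) pmin(pmax(floor(x + 0.5), 1), cap)

#' Simulate a synthetic genome with known truth
#'
#' Per gene: draw the SNP count \eqn{J_g} and mean total count
#' \eqn{\bar n_g}; draw per-SNP means on the log scale with the
#' `alpha1`/`alpha2` spread and per-cell totals with the `alpha3`/`alpha4`
#' spread (exponentiated, rounded half away from zero, floored at one read);
#' assign the true model by block; draw \eqn{\beta_g} from the grid (models
#' 2, 4), \eqn{\sigma^2_{sg} \sim IG(a_s, b_s)} (models 3, 4) and
#' \eqn{\sigma^2_{rg} \sim IG(a_r, b_r)} (always); draw the Gaussian SNP and
#' replicate effects, form \eqn{p_{gjk}} by the inverse logit and
#' \eqn{y_{gjk} \sim \mathrm{Binomial}(n_{gjk}, p_{gjk})}.
#'
#' @param cfg a [sim_config()].
#' @param rep_index replicate number (>= 1); seeds a distinct RNG stream
#'   derived from `cfg$seed`.
#' @return list with `dataset` (an [ase_dataset()]) and `truth`, a data
#'   frame with columns `gene`, `true_model`, `beta`, `sigma2_s`,
#'   `sigma2_r`.
#' @export
simulate_genome <- function(cfg, rep_index = 1L) {
  stopifnot(inherits(cfg, "sim_config"), rep_index >= 1L)
  set.seed((cfg$seed %% 59999L) * 33301L + 7L * as.integer(rep_index))

  G <- cfg$G
  K <- cfg$K
  hp <- cfg$hp
  true_model <- rep.int(1:4, cfg$genes_per_model)
  ids <- sprintf("g%05d", seq_len(G))
  rep_ids <- paste0("r", seq_len(K))

  J_all <- sample(cfg$snp_table$J, G, replace = TRUE,
                  prob = cfg$snp_table$weight)
  nbar_g <- exp(stats::rnorm(G, cfg$base_meanlog, cfg$base_sdlog))
  beta <- ifelse(true_model %in% c(2L, 4L),
                 sample(cfg$beta_grid, G, replace = TRUE), 0)
  sigma2_s <- ifelse(true_model %in% c(3L, 4L),
                     rinvgamma(G, hp$a_s, hp$b_s), 0)
  sigma2_r <- rinvgamma(G, hp$a_r, hp$b_r)

  genes <- vector("list", G)
  for (g in seq_len(G)) {
    J <- J_all[[g]]
    sd1 <- lognormal_sd(log(nbar_g[[g]]), cfg$alpha1, cfg$alpha2,
                        cfg$snp_sd_mode, cfg$sd_floor)
    log_nbar_gj <- stats::rnorm(J, log(nbar_g[[g]]), sd1)
    sd2 <- lognormal_sd(log_nbar_gj, cfg$alpha3, cfg$alpha4,
                        cfg$snp_sd_mode, cfg$sd_floor)
    n <- matrix(0, J, K)
    for (j in seq_len(J))
      n[j, ] <- round_count(exp(stats::rnorm(K, log_nbar_gj[[j]], sd2[[j]])),
                            cfg$count_cap)
    S <- stats::rnorm(J, 0, sqrt(sigma2_s[[g]]))
    R <- stats::rnorm(K, 0, sqrt(sigma2_r[[g]]))
    eta <- beta[[g]] + outer(S, R, `+`)
    p <- stats::plogis(eta)
    y <- matrix(stats::rbinom(J * K, as.integer(n), p), J, K)
    genes[[g]] <- ase_counts(ids[[g]], y, n,
                             snp_ids = paste0("s", seq_len(J)),
                             rep_ids = rep_ids)
  }

  truth <- data.frame(gene = ids, true_model = true_model, beta = beta,
                      sigma2_s = sigma2_s, sigma2_r = sigma2_r,
                      stringsAsFactors = FALSE)
  list(dataset = ase_dataset(genes,
         provenance = sprintf("simulated: seed=%d rep=%d G=%d",
                              cfg$seed, rep_index, G)),
       truth = truth)
}

#' Write simulation truth as TSV
#' @param truth truth data frame from [simulate_genome()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
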