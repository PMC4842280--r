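#' Collection sites of the 15-population survey
#'
#' The published site table of the Anopheles sinensis survey: site
#' abbreviation, decimal-degree coordinates (converted from degree-minute
#' strings), region (southwest / south / central China), and the number
#' of sequenced chromosomes per site. Used as the geographic scaffold of
#' the survey-mimic synthetic configuration.
#'
#' @return data.frame with columns `population`, `latitude`, `longitude`,
#'   `region`, `n_chromosomes`.
#' @export
ansinensis_sites <- function() {
  df <- data.frame(
    population = c("YNLH", "YNNE", "SCNJ", "GXBS", "GZLD", "GZCJ", "GXLZ",
                   "HNBT", "GDQY", "FJXM", "HBWX", "HNXY", "JSSN", "AHWH",
                   "SDHZ"),
    lat_dm = c("24°51'", "23°03'", "29°40'", "23°23'",
               "25°25'", "25°44'", "25°45'", "18°38'",
               "23°40'", "24°25'", "29°50'", "32°06'",
               "33°52'", "33°09'", "34°46'"),
    lon_dm = c("98°18'", "101°02'", "104°57'", "105°49'",
               "106°45'", "108°54'", "109°36'", "109°46'",
               "113°03'", "118°24'", "115°33'", "114°01'",
               "117°59'", "117°51'", "116°06'"),
    region = c("southwest", "southwest", "southwest",
               "south", "south", "south", "south", "south", "south", "south",
               "central", "central", "central", "central", "central"),
    n_chromosomes = c(42L, 32L, 44L, 22L, 32L, 40L, 32L, 30L, 36L, 26L,
                      42L, 38L, 30L, 62L, 38L),
    stringsAsFactors = FALSE)
  df$latitude <- parse_dms(df$lat_dm)
  df$longitude <- parse_dms(df$lon_dm)
  df[, c("population", "latitude", "longitude", "region", "n_chromosomes")]
}

#' Survey-mimic simulation configuration
#'
#' The study-condition defaults of the synthetic generator: 15 demes at
#' the published site coordinates and sample sizes (546 chromosomes in
#' all), three regions with high within-region and low between-region
#' migration (the southwest nearly isolated), sudden expansion in every
#' deme except the two Yunnan sites (which stay constant-size), and a
#' selective sweep driving the L1014F resistant codon to frequency 0.95
#' on two intron backgrounds in the five central demes.
#'
#' @param seed RNG seed for [simulate_dataset()].
#' @param theta_per_site per-site scaled mutation rate of the intron
#'   regions.
#' @return a [sim_config()].
#' @export
survey_config <- function(seed = 1L, theta_per_site = 0.004) {
  sites <- ansinensis_sites()
  D <- nrow(sites)
  region <- sites$region
  mig <- matrix(0.01, D, D)                 # southwest nearly isolated
  for (i in seq_len(D)) {
    for (j in seq_len(D)) {
      if (i == j) next
      if (region[i] == region[j]) {
        mig[i, j] <- 5
      } else if (region[i] != "southwest" && region[j] != "southwest") {
        mig[i, j] <- 0.1                    # south <-> central corridor
      }
    }
  }
  demog <- lapply(seq_len(D), function(d) {
    if (sites$population[d] %in% c("YNLH", "YNNE")) NULL
    else list(tau = 6, ratio = 0.02)
  })
  sim_config(
    n_demes = D,
    samples_per_deme = sites$n_chromosomes,
    migration = mig,
    theta_per_site = theta_per_site,
    layout = kdr_layout(),
    demography = demog,
    sweep = list(demes = sites$population[region == "central"],
                 allele = "F", final_frequency = 0.95,
                 background_count = 2L),
    coords = sites[, c("population", "latitude", "longitude", "region")],
    divergence_time = 8,
    seed = seed)
}
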