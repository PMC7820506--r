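# shared fixtures built in code

# one site with N domains at a position
one_site <- function(N = 1, pos = c(0, 0)) list(docking_site(1L, pos, N))

# many independent single-position sites
n_sites <- function(n, N = 1, pos = c(0, 0)) {
  lapply(seq_len(n), function(i) docking_site(i, pos, N))
}

# render a stack containing given emitters (data frame x_nm, y_nm, t_start,
# t_end) with chosen noise, 100 ms frames
render_fixture <- function(emitters, duration, noise, field_px = c(32L, 32L),
                           conc = 0, seed = 99) {
  ev <- if (nrow(emitters) == 0L) empty_events_fixture() else
    data.frame(site_id = seq_len(nrow(emitters)), domain_index = 1L,
               t_start = emitters$t_start, t_end = emitters$t_end,
               x_nm = emitters$x_nm, y_nm = emitters$y_nm,
               specific = TRUE)
  cfg <- kinetic_config(max(conc, 1e-30), duration, frame_time = 0.1,
                        seed = seed)
  cfg$imager_conc <- conc
  render_frames(ev, optics_model(), noise, cfg, field_px = field_px)
}

empty_events_fixture <- function() {
  data.frame(site_id = integer(0), domain_index = integer(0),
             t_start = numeric(0), t_end = numeric(0), x_nm = numeric(0),
             y_nm = numeric(0), specific = logical(0))
}

# simulate a pooled blink trace for a tile with n_sites sites of n_repeats
# domains each, and return its dark-time set
tile_trace_darks <- function(n_sites_tile, n_repeats, conc, duration,
                             imager = default_imager(), frame_time = 0.1) {
  sites <- lapply(seq_len(n_sites_tile),
                  function(i) docking_site(i, c(0, 0), n_repeats))
  sim <- simulate_specific(sites, imager,
                           kinetic_config(conc, duration, frame_time))
  extract_dark_times(sim$events, frame_time)
}
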