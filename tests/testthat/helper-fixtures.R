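# Shared fixture builders: small synthetic songs and generator settings.

make_md <- function(song_id = "s1", length_s = 220, vocal = 30, chorus = 75,
                    release = "2014-09-01", peak = "2015-01-06") {
  song_metadata(song_id, length_s, release, peak, vocal, chorus)
}

# a modest-sized default generator setup for unit tests
make_cfg <- function(seed = 1L, n_queries = 5000L, ...) {
  synth_config(seed = seed, n_queries = n_queries, ...)
}

# dataset with hand-picked offsets/dates on a fixed song
toy_dataset <- function(offsets, dates = "2015-02-01", md = make_md()) {
  query_dataset(offsets, dates, md)
}
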