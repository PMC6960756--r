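keyword,axis,p_value
excited,valence,4.59e-8
happy,valence,7.89e-9
pleased,valence,4.66e-9
peaceful,valence,7.79e-10
calm,valence,1.45e-5
gloomy,valence,3.70e-3
sad,valence,2.24e-6
fear,valence,1.58e-6
suspense,valence,6.33e-4
excited,arousal,1.02e-1
happy,arousal,1.34e-1
pleased,arousal,2.48e-1
peaceful,arousal,2.51e-1
calm,arousal,6.13e-1
gloomy,arousal,6.88e-8
sad,arousal,4.25e-8
fear,arousal,7.32e-2
suspense,arousal,3.38e-5
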