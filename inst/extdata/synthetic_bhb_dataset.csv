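"dose_mg_per_kg","time_h","mean_mM","sem_mM","n"
192,0,0.0581670932589525,0.00374899312859159,7
192,0.25,0.20166797006265,0.0125968153214269,8
192,0.5,0.778799902112481,0.0468732106111329,8
192,0.75,1.3968562037812,0.0818245812150719,8
192,1,1.7578867731211,0.0906981158386718,8
192,1.5,2.37078561315218,0.144755254167363,8
192,2,2.31349770760342,0.117430512718197,8
192,3,1.62980679520884,0.0760983066321572,8
192,4,0.873936282687963,0.0436437280907727,8
192,6,0.276568726627549,0.0139718489078628,8
573,0,0.0498815439279478,0.00754391327570132,8
573,0.25,0.486433479819536,0.0209816538592242,8
573,0.5,1.92607059840202,0.0889871894285902,8
573,0.75,3.23377953052365,0.23649774846995,8
573,1,4.76602206497255,0.302463771231147,8
573,1.5,6.86639983692657,0.449536528388503,8
573,2,8.47840546639948,0.585112768620812,8
573,3,9.76382484054216,0.412559078414525,8
573,4,8.76079416011468,0.35977707857496,8
573,6,1.78840152716369,0.112713830480627,8
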