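>P07900|561-697 human Hsp90-alpha CTD fragment (offline transcription)
QEEKKTKFENLCKIMKDILEKKVEKVVVSNRLVTSPCCIVTSTYGWTANMERIMKAQALRDNSTMGYMAAKKHLEINPDHSIIETLRQKAEADKNDKSVKDLVILLYETALLSSGFSLEDPQTHANRIYRMIKLGLG
>P02829|540-677 yeast Hsp82 CTD fragment (approximate offline transcription)
KEELKEKFEGLCKVIKDVLGDKVEKVIVSHKLVGSPAVVRTGQFGWSANMERIMKAQALRDSSMSSYMSSKKTFEISPKSPIILDALRKRAEADKNDKSVKDLVILLYETALLSSGFSLDDPNTFAARIHRMLKLGLS
>P0A6Z3|510-624 E. coli HtpG CTD fragment (approximate offline transcription)
PLAERLKEMLGDRVKEVRLTHRLTDTPAIVTTDADEMSTQMAKLFAAAGQKVPEVKYIFELNPDHVLVKRAADTEDEARFSEWVELLLDQALLAERGTLEDPNQFIRRMNQLLVS
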